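#' Construct a transcriptional unit
#'
#' A transcriptional unit (TU) is one (possibly polycistronic) mRNA: an RNA
#' sequence plus positioned gene features. Coordinates are 0-based half-open
#' internally; the GFF3 writer/reader converts to/from 1-based inclusive.
#'
#' @param tu_id Character id.
#' @param sequence RNA string (T accepted on input, mapped to U).
#' @param features data.frame with columns `gene_id`, `region` (one of
#'   `"5'UTR"`, `"CDS"`, `"3'UTR"`), `start`, `end` (0-based half-open).
#' @return An object of class `"tu"`.
#' @export
tu <- function(tu_id, sequence, features) {
  sequence <- normalize_rna(sequence)
  stopifnot(is.data.frame(features),
            all(c("gene_id", "region", "start", "end") %in% names(features)))
  stopifnot(all(features$region %in% c("5'UTR", "CDS", "3'UTR")))
  if (nrow(features)) {
    stopifnot(all(features$start >= 0), all(features$end <= nchar(sequence)),
              all(features$start < features$end))
    # within a gene, regions must not overlap
    for (g in unique(features$gene_id)) {
      f <- features[features$gene_id == g, ]
      f <- f[order(f$start), ]
      if (nrow(f) > 1 && any(f$start[-1] < f$end[-nrow(f)])) {
        stop("overlapping features within gene ", g)
      }
    }
  }
  structure(list(tu_id = tu_id, sequence = sequence,
                 features = features[order(features$start), , drop = FALSE]),
            class = "tu")
}

#' Construct a TU collection
#'
#' @param tus List of [tu()] objects with unique ids.
#' @return An object of class `"tu_set"` (a named list).
#' @export
tu_set <- function(tus) {
  stopifnot(all(vapply(tus, inherits, TRUE, "tu")))
  ids <- vapply(tus, function(x) x$tu_id, "")
  if (anyDuplicated(ids)) stop("duplicate TU ids")
  structure(setNames(tus, ids), class = "tu_set")
}

#' @export
print.tu_set <- function(x, ...) {
  cat("tu_set with", length(x), "transcriptional units,",
      sum(vapply(x, function(t) nrow(t$features), 0L)), "features\n")
  invisible(x)
}

# random RNA with no consensus occurrence: every accidental hit is destroyed
# by rewriting its first uridine to C (no pattern contains C, so the edit can
# never create a new hit); loop until the scanner reports zero hits
scrub_consensus <- function(len) {
  s <- paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  repeat {
    h <- find_motif_hits(s)
    if (!nrow(h)) return(s)
    for (o in h$offset) substr(s, o + 2L, o + 2L) <- "C"
  }
}

#' Generate a synthetic transcriptome with planted Musashi motifs
#'
#' Emulates a bacterial TU reference (polycistronic mRNAs with 5'UTR/CDS
#' features and a terminal 3'UTR) in which the number of consensus
#' occurrences per TU is known exactly: background sequence is
#' rejection-sampled so it contains no accidental RU_nAGU match, then the
#' planned number of motifs is spliced in at recorded offsets and the TU is
#' re-scanned to verify the planted set is exactly what a scanner will find.
#'
#' @param n_tus Number of TUs.
#' @param genes_per_tu Integer vector to sample the per-TU gene count from
#'   (default `1:3`).
#' @param motif_plan Named integer vector, TU id (`"TU0001"`, ...) to number
#'   of planted occurrences; TUs not named get 0. Default: none.
#' @param seed Integer seed (determinism contract: same seed, same output).
#' @param utr_len,cds_codons Ranges to sample 5'/3'UTR lengths and CDS codon
#'   counts from.
#' @return List with `tus` (a [tu_set()]) and `truth` (list per TU:
#'   data.frame `offset`, `pattern`).
#' @export
gen_transcriptome <- function(n_tus, genes_per_tu = 1:3,
                              motif_plan = integer(), seed = 1,
                              utr_len = 20:60, cds_codons = 30:100) {
  stopifnot(n_tus >= 1)
  set.seed(seed)
  pats <- msi_consensus_patterns()
  tu_ids <- sprintf("TU%04d", seq_len(n_tus))
  unknown <- setdiff(names(motif_plan), tu_ids)
  if (length(unknown)) stop("motif_plan names not in TU set: ",
                            paste(unknown, collapse = ", "))
  gene_counter <- 0L
  truth <- list()
  tus <- vector("list", n_tus)
  for (i in seq_len(n_tus)) {
    n_genes <- if (length(genes_per_tu) == 1) genes_per_tu else
      sample(genes_per_tu, 1)
    feats <- NULL
    pos <- 0L
    for (g in seq_len(n_genes)) {
      gene_counter <- gene_counter + 1L
      gid <- sprintf("g%04d", gene_counter)
      u5 <- sample(utr_len, 1)
      cds <- 3L * sample(cds_codons, 1)
      feats <- rbind(feats, data.frame(
        gene_id = gid, region = c("5'UTR", "CDS"),
        start = c(pos, pos + u5), end = c(pos + u5, pos + u5 + cds),
        stringsAsFactors = FALSE))
      pos <- pos + u5 + cds
    }
    u3 <- sample(utr_len, 1)
    feats <- rbind(feats, data.frame(
      gene_id = feats$gene_id[nrow(feats)], region = "3'UTR",
      start = pos, end = pos + u3, stringsAsFactors = FALSE))
    len <- pos + u3
    k <- if (tu_ids[i] %in% names(motif_plan))
      as.integer(motif_plan[[tu_ids[i]]]) else 0L
    if (k * 8L > len) stop("infeasible motif plan for ", tu_ids[i],
                           ": ", k, " occurrences in ", len, " nt")
    planted <- plant_motifs(len, k, pats)
    tus[[i]] <- tu(tu_ids[i], planted$sequence, feats)
    truth[[tu_ids[i]]] <- planted$truth
  }
  list(tus = tu_set(tus), truth = truth)
}

# splice k motifs into scrubbed background at non-overlapping offsets, then
# verify the scanner sees exactly the planted set (junctions can in rare
# cases create an extra match; retry with a fresh draw when they do)
plant_motifs <- function(len, k, pats) {
  for (attempt in 1:100) {
    s <- scrub_consensus(len)
    if (k == 0) {
      return(list(sequence = s,
                  truth = data.frame(offset = integer(), pattern = character(),
                                     stringsAsFactors = FALSE)))
    }
    chosen <- sample(pats, k, replace = TRUE)
    offsets <- integer(0)
    ok <- TRUE
    for (p in chosen) {
      cand <- setdiff(0:(len - nchar(p)),
                      unlist(lapply(seq_along(offsets), function(j) {
                        (offsets[j] - nchar(p) - 6L):(offsets[j] + 13L)
                      })))
      if (!length(cand)) { ok <- FALSE; break }
      offsets <- c(offsets, if (length(cand) == 1) cand else sample(cand, 1))
    }
    if (!ok) next
    for (j in seq_len(k)) {
      substr(s, offsets[j] + 1L, offsets[j] + nchar(chosen[j])) <- chosen[j]
    }
    found <- find_motif_hits(s)
    if (nrow(found) == k && setequal(found$offset, offsets)) {
      o <- order(offsets)
      return(list(sequence = s,
                  truth = data.frame(offset = offsets[o], pattern = chosen[o],
                                     stringsAsFactors = FALSE)))
    }
  }
  stop("could not realize motif plan (", k, " occurrences in ", len,
       " nt) without spurious matches")
}

#' Write TU sequences as FASTA
#'
#' U is written as T (DNA spelling, the common convention for deposited
#' transcript references), wrapped at 80 columns.
#'
#' @param tus A [tu_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tu_fasta <- function(tus, path) {
  seqs <- Biostrings::DNAStringSet(vapply(tus, function(t)
    chartr("U", "T", t$sequence), ""))
  names(seqs) <- vapply(tus, function(t) t$tu_id, "")
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Write TU features as GFF3
#'
#' Each TU becomes a parent `transcript` feature on its own seqid with
#' `five_prime_UTR`/`CDS`/`three_prime_UTR` children; coordinates are
#' converted from the internal 0-based half-open convention to GFF3 1-based
#' inclusive, + strand.
#'
#' @param tus A [tu_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tu_gff3 <- function(tus, path) {
  type_map <- c("5'UTR" = "five_prime_UTR", "CDS" = "CDS",
                "3'UTR" = "three_prime_UTR")
  rows <- lapply(tus, function(t) {
    f <- t$features
    data.frame(
      seqid = t$tu_id,
      type = c("transcript", unname(type_map[f$region])),
      start = c(1L, f$start + 1L),
      end = c(nchar(t$sequence), f$end),
      ID = c(t$tu_id, sprintf("%s:%s:%d", f$gene_id, f$region, f$start)),
      Parent = c(NA, rep(t$tu_id, nrow(f))),
      gene = c(NA, f$gene_id),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  gr <- GenomicRanges::GRanges(
    seqnames = tab$seqid,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = "+")
  S4Vectors::mcols(gr)$type <- tab$type
  S4Vectors::mcols(gr)$phase <- ifelse(tab$type == "CDS", 0L, NA_integer_)
  S4Vectors::mcols(gr)$ID <- tab$ID
  S4Vectors::mcols(gr)$Parent <- tab$Parent
  S4Vectors::mcols(gr)$gene <- tab$gene
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a TU collection from FASTA + GFF3
#'
#' Inverse of [write_tu_fasta()]/[write_tu_gff3()]: sequences are mapped back
#' to the RNA alphabet and GFF3 coordinates to 0-based half-open.
#'
#' @param fasta_path,gff3_path Input paths.
#' @return A [tu_set()].
#' @export
read_tu_set <- function(fasta_path, gff3_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  gff <- rtracklayer::import(gff3_path, format = "gff3")
  type_map <- c(five_prime_UTR = "5'UTR", CDS = "CDS",
                three_prime_UTR = "3'UTR")
  tus <- lapply(names(seqs), function(id) {
    g <- gff[GenomicRanges::seqnames(gff) == id &
               S4Vectors::mcols(gff)$type %in% names(type_map)]
    feats <- data.frame(
      gene_id = as.character(S4Vectors::mcols(g)$gene),
      region = unname(type_map[as.character(S4Vectors::mcols(g)$type)]),
      start = GenomicRanges::start(g) - 1L,
      end = GenomicRanges::end(g),
      stringsAsFactors = FALSE)
    tu(id, as.character(seqs[[id]]), feats)
  })
  tu_set(tus)
}
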