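#' The Musashi consensus patterns RU_nAGU (n = 1-3)
#'
#' Musashi RRM1 recognizes single-stranded RNA matching the degenerate
#' consensus RU_nAGU with R a purine (A or G) and a run of one to three
#' uridines, giving six concrete patterns of lengths 5-7 nt.
#'
#' @return Character vector of the six patterns, RNA alphabet.
#' @examples
#' msi_consensus_patterns()
#' @export
msi_consensus_patterns <- function() {
  as.character(vapply(1:3, function(n) {
    paste0(c("A", "G"), strrep("U", n), "AGU")
  }, character(2)))
}

# T -> U, uppercase; error (with position) on anything outside {A,C,G,U}
normalize_rna <- function(sequence) {
  s <- chartr("t", "u", chartr("T", "U", toupper(sequence)))
  bad <- regexpr("[^ACGU]", s)
  if (bad > 0) {
    stop("non-nucleotide character '", substr(s, bad, bad),
         "' at position ", bad, call. = FALSE)
  }
  s
}

#' Find all Musashi consensus hits in one RNA sequence
#'
#' Scans the sense strand for every occurrence of RU_nAGU (n = 1-3),
#' including overlapping occurrences. At a given offset at most one n can
#' match (the base after the U-run differs), so each offset yields at most
#' one hit; hits are reported sorted by offset.
#'
#' @param sequence RNA (or DNA; T is mapped to U) character string.
#' @return A data.frame with columns `offset` (0-based start), `length`
#'   (5-7), `n` (number of uridines, 1-3), `r_base` ("A" or "G") and
#'   `pattern` (the matched string). Zero rows when nothing matches.
#' @examples
#' find_motif_hits("AUAGUAGU")   # two overlapping hits
#' @export
find_motif_hits <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  s <- normalize_rna(sequence)
  # zero-width lookahead so overlapping occurrences are all reported;
  # U{1,3} is greedy but at a fixed offset only one n can match anyway
  m <- gregexpr("(?=([AG]U{1,3}AGU))", s, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(offset = integer(), length = integer(), n = integer(),
                      r_base = character(), pattern = character(),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(m)
  len <- as.integer(attr(m, "capture.length")[, 1])
  data.frame(
    offset = start - 1L,
    length = len,
    n = len - 4L,
    r_base = substr(s, start, start),
    pattern = substring(s, start, start + len - 1L),
    stringsAsFactors = FALSE
  )
}

#' Scan a collection of transcriptional units for the Musashi consensus
#'
#' Applies [find_motif_hits()] to every TU and annotates each hit with the
#' feature (5'UTR/CDS/3'UTR and gene) containing its start position. A TU is
#' flagged `duplicate` when it carries two or more occurrences, the criterion
#' for engagement of both RRMs of the protein.
#'
#' @param tus A [tu_set()] collection.
#' @param max_spacing Optional maximal distance (nt, between hit start
#'   offsets) for two occurrences to count as a duplicate; `Inf` (default)
#'   accepts any two occurrences anywhere in the TU.
#' @return A list with elements
#'   \describe{
#'     \item{hits}{data.frame: `tu_id`, `offset`, `length`, `n`, `r_base`,
#'       `pattern`, `region` (e.g. `"CDS:g0002"` or `"unannotated"`).}
#'     \item{report}{data.frame: one row per TU with `tu_id`, `count`,
#'       `duplicate` (`count >= 2`, within `max_spacing` when set),
#'       `regions` (comma-collapsed).}
#'   }
#' @export
scan_transcriptome <- function(tus, max_spacing = Inf) {
  stopifnot(inherits(tus, "tu_set"))
  per_tu <- lapply(tus, function(tu) {
    h <- find_motif_hits(tu$sequence)
    if (nrow(h)) {
      h$tu_id <- tu$tu_id
      h$region <- vapply(h$offset, function(o) annotate_offset(o, tu), "")
    } else {
      h$tu_id <- character()
      h$region <- character()
    }
    h[, c("tu_id", "offset", "length", "n", "r_base", "pattern", "region")]
  })
  hits <- do.call(rbind, c(per_tu, list(make.row.names = FALSE)))
  if (is.null(hits)) {
    hits <- data.frame(tu_id = character(), offset = integer(),
                       length = integer(), n = integer(), r_base = character(),
                       pattern = character(), region = character(),
                       stringsAsFactors = FALSE)
  }
  counts <- vapply(per_tu, nrow, 0L)
  dup <- vapply(per_tu, function(h) {
    nrow(h) >= 2L && min(diff(sort(h$offset))) <= max_spacing
  }, TRUE)
  report <- data.frame(
    tu_id = vapply(tus, function(tu) tu$tu_id, ""),
    count = counts,
    duplicate = dup,
    regions = vapply(per_tu, function(h) paste(h$region, collapse = ","), ""),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  list(hits = hits, report = report)
}

# feature label at a 0-based offset within a TU; convention: a hit spanning a
# boundary is labelled by its start position
annotate_offset <- function(offset, tu) {
  f <- tu$features
  i <- which(f$start <= offset & offset < f$end)
  if (!length(i)) return("unannotated")
  paste0(f$region[i[1]], ":", f$gene_id[i[1]])
}

#' Annotate a single motif hit with its containing feature
#'
#' @param hit One row of the `hits` table from [scan_transcriptome()] or
#'   [find_motif_hits()] (needs an `offset` column).
#' @param tu The [tu()] the hit belongs to.
#' @return Label `"region:gene"`, or `"unannotated"` when no feature contains
#'   the hit's start.
#' @export
annotate_hit <- function(hit, tu) {
  offset <- hit$offset
  stopifnot(length(offset) == 1, offset >= 0)
  if (offset >= nchar(tu$sequence)) stop("hit offset out of bounds")
  annotate_offset(offset, tu)
}

#' Classify TE-regulated genes as direct or indirect Musashi targets
#'
#' A gene whose translation efficiency responds to MSI-1* is a
#' direct-candidate only when its transcriptional unit carries the binding
#' motif (by default in duplicate, one site per RRM); a responding gene
#' without motif support is classified indirect (burden or downstream
#' effects), and everything else unaffected.
#'
#' @param te_results data.frame from [te_test()] (columns `gene`, `call`).
#' @param reports `report` table from [scan_transcriptome()].
#' @param gene_to_tu Named character vector mapping gene id to TU id.
#' @param require_duplicate Require >= 2 motif occurrences (default) rather
#'   than >= 1.
#' @return data.frame `gene`, `tu_id`, `te_call`, `motif_count`, `class`
#'   (`"direct-candidate"`, `"indirect"` or `"unaffected"`). TE-significant
#'   genes with no TU mapping are dropped with a warning.
#' @export
call_direct_targets <- function(te_results, reports, gene_to_tu,
                                require_duplicate = TRUE) {
  stopifnot(is.data.frame(te_results), is.data.frame(reports))
  sig <- te_results$call %in% c("up", "down")
  unmapped <- sig & !(te_results$gene %in% names(gene_to_tu))
  if (any(unmapped)) {
    warning("dropping TE-significant gene(s) without a TU mapping: ",
            paste(te_results$gene[unmapped], collapse = ", "))
  }
  keep <- !unmapped
  res <- te_results[keep, c("gene", "call")]
  names(res)[2] <- "te_call"
  res$tu_id <- unname(gene_to_tu[res$gene])
  idx <- match(res$tu_id, reports$tu_id)
  res$motif_count <- reports$count[idx]
  res$motif_count[is.na(res$motif_count)] <- 0L
  # the duplicate flag carries any spacing criterion the scan applied
  supported <- if (require_duplicate) {
    !is.na(idx) & reports$duplicate[idx]
  } else {
    res$motif_count >= 1L
  }
  sig <- res$te_call %in% c("up", "down")
  res$class <- ifelse(!sig, "unaffected",
                      ifelse(supported, "direct-candidate", "indirect"))
  res[, c("gene", "tu_id", "te_call", "motif_count", "class")]
}

#' Write motif hits as BED6 (TU-relative coordinates)
#'
#' Coordinates are 0-based half-open as in BED; `name` is the matched
#' pattern and `score` the number of uridines.
#'
#' @param hits `hits` table from [scan_transcriptome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(hits$tu_id, hits$offset, hits$offset + hits$length,
                    hits$pattern, hits$n, "+")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
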