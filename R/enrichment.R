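#' One-sided Fisher exact test for a 2x2 enrichment table
#'
#' Tests over-representation of a term among a gene list drawn from a
#' universe: with `k` list members in a term of size `K`, list size `n` and
#' universe size `N`, the p-value is the hypergeometric upper tail
#' `P(X >= k)`. The sample odds ratio is computed from the 2x2 table with a
#' Haldane correction of 0.5 added to every cell when any cell is zero (the
#' p-value is never corrected).
#'
#' @param k Hits in the list. @param K Term size. @param n List size.
#' @param N Universe size.
#' @return List with `odds_ratio` and `p`.
#' @examples
#' fisher_2x2(5, 5, 5, 20)  # p = 1 / choose(20, 5)
#' @export
fisher_2x2 <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= 1)
  if (k > K || k > n || K > N || n > N || (n - k) > (N - K)) {
    stop("inconsistent 2x2 margins")
  }
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  a <- k; b <- n - k; cc <- K - k; d <- N - K - n + k
  if (min(a, b, cc, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  list(odds_ratio = (a * d) / (b * cc), p = p)
}

#' Term enrichment of a gene list against a universe
#'
#' One row per term (terms smaller than `min_term_size` are skipped), BH
#' correction across tested terms, sorted by adjusted p then term id.
#'
#' @param gene_list Character vector of genes of interest; genes outside the
#'   universe are reported and dropped.
#' @param term_map Named list: term id to character vector of member genes
#'   (members outside the universe are dropped).
#' @param universe Character vector, the gene universe.
#' @param alpha Adjusted-p cutoff for the `enriched` flag.
#' @param min_term_size Minimal term size tested (default 3).
#' @return data.frame: `term`, `k`, `K`, `n`, `N`, `gene_ratio`,
#'   `odds_ratio`, `p`, `padj`, `enriched`.
#' @export
enrich <- function(gene_list, term_map, universe, alpha = 0.05,
                   min_term_size = 3) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    warning("dropping gene(s) outside the universe: ",
            paste(outside, collapse = ", "))
    gene_list <- intersect(gene_list, universe)
  }
  n <- length(gene_list)
  N <- length(universe)
  members <- lapply(term_map, function(g) intersect(unique(g), universe))
  keep <- vapply(members, length, 0L) >= min_term_size
  members <- members[keep]
  if (!length(members)) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), gene_ratio = numeric(),
                      odds_ratio = numeric(), p = numeric(), padj = numeric(),
                      enriched = logical(), stringsAsFactors = FALSE))
  }
  rows <- lapply(names(members), function(tm) {
    K <- length(members[[tm]])
    k <- length(intersect(gene_list, members[[tm]]))
    ft <- fisher_2x2(k, K, n, N)
    data.frame(term = tm, k = k, K = K, n = n, N = N,
               gene_ratio = if (n > 0) k / n else NA_real_,
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res$padj <- bh_adjust(res$p)
  res$enriched <- res$padj < alpha
  res[order(res$padj, res$term), , drop = FALSE]
}

#' Read a term map from a two-column TSV (term, gene) or GMT file
#'
#' @param path Input path. Files ending in `.gmt` are parsed as GMT
#'   (term, description, members...); anything else as headerless
#'   two-column TSV.
#' @return Named list term -> character vector of genes.
#' @export
read_term_map <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    setNames(lapply(parts, function(x) x[-(1:2)]),
             vapply(parts, `[`, "", 1))
  } else {
    df <- read.delim(path, header = FALSE, col.names = c("term", "gene"))
    split(as.character(df$gene), df$term)
  }
}
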