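#' Median-of-ratios size factors
#'
#' The standard RNA-seq library-size normalization: each sample's factor is
#' the median, over genes with a positive geometric mean across samples, of
#' the ratio of the gene's count to that geometric mean.
#'
#' @param counts Nonnegative genes x samples matrix.
#' @return Positive numeric vector, one factor per sample.
#' @examples
#' m <- cbind(a = c(10L, 20L), b = c(20L, 40L))
#' rownames(m) <- c("g1", "g2")
#' estimate_size_factors(m)  # (1/sqrt(2), sqrt(2))
#' @export
estimate_size_factors <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use)) {
    stop("degenerate input: no gene has nonzero counts in every sample")
  }
  sf <- apply(counts, 2, function(col) {
    exp(median(log(col[use]) - loggeo[use]))
  })
  unname(sf)
}

#' Method-of-moments NB dispersion estimation
#'
#' Per gene, the sample variance of normalized counts is pooled within
#' condition (so planted condition effects do not inflate it) and the
#' dispersion solved from the NB variance function `var = mu + alpha mu^2`:
#' `alpha_i = (s2_i - mu_i) / mu_i^2`. Three policies are offered:
#'
#' * `"moderated"` (default): gene-wise estimates are shrunk toward the
#'   pooled value with weight `df_gene / (df_gene + prior_df)` and floored at
#'   the pooled value. At low replication gene-wise moments are noisy; the
#'   floor keeps genes with visibly elevated scatter from being tested with
#'   an optimistic variance while the shrinkage keeps power.
#' * `"per-gene"`: raw gene-wise estimates clamped at `floor`.
#' * `"pooled"`: one common value for all genes, the ratio-of-sums estimator
#'   `sum(s2_i - mu_i) / sum(mu_i^2)` over genes with `mu_i >= 1` (an
#'   unclamped mean would be dominated by low-expression genes, a clamped
#'   median is biased low at 2 degrees of freedom).
#'
#' @param counts Genes x samples count matrix.
#' @param size_factors Per-sample positive factors.
#' @param condition Per-sample condition labels.
#' @param mode One of `"moderated"`, `"per-gene"`, `"pooled"`.
#' @param prior_df Prior degrees of freedom for moderation (default 8).
#' @param floor Lower bound applied to the returned values.
#' @return Named numeric vector of per-gene dispersions; all-zero genes get
#'   `NA` (untestable). The pooled value is attached as
#'   `attr(, "pooled")`.
#' @export
estimate_dispersion <- function(counts, size_factors, condition,
                                mode = c("moderated", "per-gene", "pooled"),
                                prior_df = 8, floor = 0) {
  mode <- match.arg(mode)
  stopifnot(all(size_factors > 0), ncol(counts) == length(size_factors),
            length(condition) == ncol(counts))
  norm <- sweep(counts, 2, size_factors, "/")
  conds <- unique(condition)
  df_gene <- sum(vapply(conds, function(cc) sum(condition == cc) - 1L, 0L))
  if (df_gene < 1) stop("need >= 2 replicates in at least one condition")
  mu_g <- rowMeans(vapply(conds, function(cc)
    rowMeans(norm[, condition == cc, drop = FALSE]), numeric(nrow(norm))))
  s2_g <- rowSums(vapply(conds, function(cc) {
    sub <- norm[, condition == cc, drop = FALSE]
    if (ncol(sub) < 2) return(numeric(nrow(norm)))
    apply(sub, 1, var) * (ncol(sub) - 1L)
  }, numeric(nrow(norm)))) / df_gene
  raw <- (s2_g - mu_g) / mu_g^2
  expressed <- mu_g >= 1
  pooled <- max(0, sum(s2_g[expressed] - mu_g[expressed]) /
                  sum(mu_g[expressed]^2))
  alpha <- switch(mode,
    "per-gene" = pmax(floor, raw),
    "pooled" = rep(max(floor, pooled), nrow(counts)),
    "moderated" = {
      w <- df_gene / (df_gene + prior_df)
      pmax(max(floor, pooled), w * pmax(0, raw) + (1 - w) * pooled)
    })
  alpha[mu_g == 0] <- NA_real_
  names(alpha) <- rownames(counts)
  attr(alpha, "pooled") <- pooled
  alpha
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]` (`NA` passed
#'   through).
#' @return Adjusted p-values, capped at 1, `padj >= p` elementwise.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Classify differential-expression calls
#'
#' The call rule used throughout: significant (`padj < alpha`) and a linear
#' fold change beyond `min_fold` in either direction; everything else `ns`.
#'
#' @param padj BH-adjusted p-values.
#' @param log2fc Log2 fold changes (MSI vs control).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param min_fold Minimal linear fold change (default 1.5).
#' @return Character vector in `{"up", "down", "ns"}`; `NA` stats give
#'   `"ns"`.
#' @export
classify_de <- function(padj, log2fc, alpha = 0.05, min_fold = 1.5) {
  fold <- 2^log2fc
  call <- rep("ns", length(padj))
  sig <- !is.na(padj) & !is.na(fold) & padj < alpha
  call[sig & fold > min_fold] <- "up"
  call[sig & fold < 1 / min_fold] <- "down"
  call
}

#' Negative-binomial Wald test for a two-condition contrast
#'
#' Per gene, the log2 fold change is the log ratio of condition means of
#' normalized counts; its standard error follows from the NB variance of
#' each group mean (`var(q_ij) = mu/sf_j + alpha mu^2` for a normalized
#' count), the Wald statistic is `log2fc / se` and two-sided p-values come
#' from the standard normal. A pseudo-count (default 0.5) replaces a group
#' mean of zero so the fold change stays finite; genes with fewer than
#' `min_count` total raw counts are flagged `low_count` and excluded from
#' testing and from the BH family.
#'
#' @param counts Genes x samples count matrix (rownames = gene ids).
#' @param size_factors Per-sample factors (default: estimated from
#'   `counts`).
#' @param dispersions Per-gene NB dispersions (default: estimated with
#'   [estimate_dispersion()], moderated mode).
#' @param condition Per-sample labels; exactly two levels, contrast is
#'   second vs first in the order given by `ref` and its complement.
#' @param ref Reference (denominator) condition, default `"control"`.
#' @param alpha,min_fold Call rule parameters, see [classify_de()].
#' @param min_count Minimal total raw count for a gene to be testable.
#' @param pseudo Pseudo-count for zero group means (set `NA` to disable and
#'   drop such genes as untestable).
#' @return data.frame: `gene`, `base_mean`, `log2fc`, `se`, `wald`, `p`,
#'   `padj`, `call`.
#' @export
wald_test <- function(counts, size_factors = NULL, dispersions = NULL,
                      condition, ref = "control", alpha = 0.05,
                      min_fold = 1.5, min_count = 10, pseudo = 0.5) {
  stopifnot(is.matrix(counts), length(condition) == ncol(counts))
  lv <- unique(condition)
  if (length(lv) != 2) stop("exactly two conditions required")
  if (!ref %in% lv) stop("reference condition '", ref, "' absent")
  other <- setdiff(lv, ref)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion(counts, size_factors, condition)
  }
  stopifnot(length(dispersions) == nrow(counts))
  norm <- sweep(counts, 2, size_factors, "/")
  g0 <- condition == ref
  g1 <- condition == other
  m0 <- rowMeans(norm[, g0, drop = FALSE])
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  base_mean <- rowMeans(norm)
  testable <- rowSums(counts) >= min_count & !is.na(dispersions)
  if (is.na(pseudo)) {
    testable <- testable & m0 > 0 & m1 > 0
    m0p <- m0; m1p <- m1
  } else {
    m0p <- ifelse(m0 == 0, pseudo, m0)
    m1p <- ifelse(m1 == 0, pseudo, m1)
  }
  log2fc <- log2(m1p / m0p)
  # variance of a group mean of normalized NB counts, dispersion plugged in:
  # var(K_ij / sf_j) = mu / sf_j + alpha mu^2
  n0 <- sum(g0); n1 <- sum(g1)
  v0 <- (m0p * sum(1 / size_factors[g0]) + dispersions * m0p^2 * n0) / n0^2
  v1 <- (m1p * sum(1 / size_factors[g1]) + dispersions * m1p^2 * n1) / n1^2
  se <- sqrt(v0 / m0p^2 + v1 / m1p^2) / log(2)
  wald <- log2fc / se
  p <- 2 * pnorm(-abs(wald))
  res <- data.frame(gene = rownames(counts), base_mean = base_mean,
                    log2fc = log2fc, se = se, wald = wald, p = p,
                    padj = NA_real_, stringsAsFactors = FALSE,
                    row.names = NULL)
  res[!testable, c("log2fc", "se", "wald", "p")] <- NA_real_
  # stable tie-break: BH on (p, gene) ordering
  ord <- order(res$p, res$gene)
  res$padj[ord] <- bh_adjust(res$p[ord])
  res$call <- classify_de(res$padj, res$log2fc, alpha, min_fold)
  res$call[!testable] <- "low_count"
  res
}

#' Translation-efficiency test (Ribo-seq vs RNA-seq interaction)
#'
#' Translation efficiency is Ribo-seq signal normalized by RNA-seq signal; a
#' TE change is the interaction contrast: the gene's Ribo log2 fold change
#' minus its RNA log2 fold change. Each assay is tested with [wald_test()]
#' machinery (its own size factors and dispersions); the two fold changes
#' are treated as independent, so `se = sqrt(se_ribo^2 + se_rna^2)`, with
#' Wald/normal p-values, BH correction, and the same call rule as
#' transcription.
#'
#' @param experiment A [count_experiment()] with both assays.
#' @param alpha,min_fold,min_count,pseudo As in [wald_test()]; a gene must
#'   be testable in both assays.
#' @param dispersion_mode Passed to [estimate_dispersion()].
#' @return data.frame: `gene`, `log2fc_rna`, `log2fc_ribo`, `delta_te`,
#'   `se`, `wald`, `p`, `padj`, `call`.
#' @export
te_test <- function(experiment, alpha = 0.05, min_fold = 1.5,
                    min_count = 10, pseudo = 0.5,
                    dispersion_mode = "moderated") {
  stopifnot(inherits(experiment, "count_experiment"))
  if (is.null(experiment$ribo)) stop("Ribo assay missing from experiment")
  run <- function(m) {
    sf <- estimate_size_factors(m)
    disp <- estimate_dispersion(m, sf, experiment$condition,
                                mode = dispersion_mode)
    wald_test(m, sf, disp, experiment$condition, alpha = alpha,
              min_fold = min_fold, min_count = min_count, pseudo = pseudo)
  }
  rna <- run(experiment$rna)
  ribo <- run(experiment$ribo)
  delta <- ribo$log2fc - rna$log2fc
  se <- sqrt(rna$se^2 + ribo$se^2)
  wald <- delta / se
  p <- 2 * pnorm(-abs(wald))
  res <- data.frame(gene = rna$gene, log2fc_rna = rna$log2fc,
                    log2fc_ribo = ribo$log2fc, delta_te = delta,
                    se = se, wald = wald, p = p, padj = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(res$p, res$gene)
  res$padj[ord] <- bh_adjust(res$p[ord])
  res$call <- classify_de(res$padj, res$delta_te, alpha, min_fold)
  res$call[rna$call == "low_count" | ribo$call == "low_count"] <- "low_count"
  res
}

#' Write a differential-expression or TE result table as TSV
#'
#' @param result data.frame from [wald_test()] or [te_test()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(result, path) {
  write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
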