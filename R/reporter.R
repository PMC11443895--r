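#' Normalized fluorescence from raw plate-reader signals
#'
#' Medium background is subtracted from both channels, fluorescence is
#' normalized by absorbance (so the value is per-biomass), and the
#' autofluorescence of non-transformed cells is subtracted:
#' `(F_raw - F_bg) / (A_raw - A_bg) - F_auto`. Values may come out slightly
#' negative from noise; they are kept as-is so downstream error propagation
#' stays honest (clamp only for display).
#'
#' @param F_raw,A_raw Raw fluorescence and absorbance (OD600) of the well.
#' @param F_bg,A_bg Medium-only background fluorescence and absorbance.
#' @param F_auto Normalized autofluorescence of non-transformed cells.
#' @return Expression estimate in arbitrary units (vectorized).
#' @examples
#' normalized_fluorescence(1000, 0.5, 100, 0.05, 200)  # 1800
#' @export
normalized_fluorescence <- function(F_raw, A_raw, F_bg, A_bg, F_auto = 0) {
  if (any(A_raw <= A_bg)) {
    stop("absorbance at or below background: expression undefined")
  }
  (F_raw - F_bg) / (A_raw - A_bg) - F_auto
}

#' Repression exerted by the regulator
#'
#' Fractional loss of expression when the regulator is induced:
#' `1 - E_on / E_off`.
#'
#' @param E_off Expression without induction (regulator absent).
#' @param E_on Expression under induction (regulator present).
#' @return List with `fraction` and `percent` (vectorized).
#' @examples
#' repression(100, 10.8)$percent  # 89.2
#' @export
repression <- function(E_off, E_on) {
  if (any(E_off <= 0)) stop("E_off must be positive")
  frac <- 1 - E_on / E_off
  list(fraction = frac, percent = 100 * frac)
}

#' Dynamic range (fold change) of the response
#'
#' `E_off / E_on`; dual to repression: `fold = 1 / (1 - fraction)`.
#'
#' @param E_off,E_on Expression without / with induction.
#' @return Fold change; infinite (with a warning) when `E_on = 0`.
#' @export
fold_change <- function(E_off, E_on) {
  if (any(E_on < 0) || any(E_off < 0)) stop("expressions must be nonnegative")
  if (any(E_on == 0)) warning("E_on = 0: infinite fold change")
  E_off / E_on
}

#' Predicted fold change of a two-motif target under independent binding
#'
#' If the regulator occupies the RBS-proximal and AUG-proximal sites
#' independently, expression is proportional to the product of the two
#' single-site pass-through fractions, so the two-motif fold change is the
#' product of the one-motif fold changes.
#'
#' @param fc_motif_rbs Fold change of the motif-in-RBS reporter.
#' @param fc_motif_aug Fold change of the motif-after-AUG reporter.
#' @return Predicted two-motif fold change (commutative in its arguments).
#' @export
predict_two_motif_fc <- function(fc_motif_rbs, fc_motif_aug) {
  stopifnot(all(fc_motif_rbs >= 0), all(fc_motif_aug >= 0))
  fc_motif_rbs * fc_motif_aug
}

#' Compare predicted and observed fold changes
#'
#' @param predicted,observed Positive fold changes (vectorized).
#' @return data.frame with `predicted`, `observed`, `ratio`
#'   (observed/predicted) and `log2_error`, sorted by `abs(log2_error)`
#'   when more than one row.
#' @export
compare_prediction <- function(predicted, observed) {
  if (any(predicted <= 0) || any(observed <= 0)) {
    stop("fold changes must be positive")
  }
  out <- data.frame(predicted = predicted, observed = observed,
                    ratio = observed / predicted,
                    log2_error = log2(observed / predicted))
  out[order(abs(out$log2_error)), , drop = FALSE]
}

#' Reduce a raw plate table to per-genotype expression estimates
#'
#' Applies [normalized_fluorescence()] well-by-well: background values come
#' from medium-only wells, autofluorescence from the non-transformed
#' genotype (averaged over its wells after background normalization).
#'
#' @param plate data.frame with columns `well`, `genotype`, `condition`,
#'   `od600`, `fluorescence` (as produced by [gen_plate()] or
#'   [read_plate_csv()]).
#' @param blank_genotype Genotype label of medium-only wells.
#' @param autofluor_genotype Genotype label of non-transformed cells.
#' @return data.frame: `genotype`, `condition`, `n`, `mean`, `sd`,
#'   `negative` (flag: mean below zero after subtraction). Blank and
#'   autofluorescence wells are consumed, not reported.
#' @export
process_plate <- function(plate, blank_genotype = "blank",
                          autofluor_genotype = "nontransformed") {
  need <- c("well", "genotype", "condition", "od600", "fluorescence")
  stopifnot(all(need %in% names(plate)))
  blanks <- plate$genotype == blank_genotype
  if (!any(blanks)) stop("no medium-only (blank) wells found")
  F_bg <- mean(plate$fluorescence[blanks])
  A_bg <- mean(plate$od600[blanks])
  rest <- plate[!blanks, , drop = FALSE]
  norm <- normalized_fluorescence(rest$fluorescence, rest$od600, F_bg, A_bg)
  auto <- rest$genotype == autofluor_genotype
  F_auto <- if (any(auto)) mean(norm[auto]) else 0
  expr <- norm - F_auto
  rest <- rest[!auto, , drop = FALSE]
  expr <- expr[!auto]
  key <- interaction(rest$genotype, rest$condition, drop = TRUE)
  agg <- lapply(split(expr, key), function(v) {
    c(n = length(v), mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
  })
  ids <- do.call(rbind, strsplit(names(agg), ".", fixed = TRUE))
  out <- data.frame(genotype = ids[, 1], condition = ids[, 2],
                    do.call(rbind, agg), stringsAsFactors = FALSE,
                    row.names = NULL)
  out$negative <- out$mean < 0
  out <- out[order(out$genotype, out$condition), , drop = FALSE]
  # per-well values kept for the per-replicate activity estimator
  attr(out, "wells") <- data.frame(genotype = rest$genotype,
                                   condition = rest$condition,
                                   expression = expr,
                                   stringsAsFactors = FALSE)
  out
}

#' Regulator activity from per-genotype expression estimates
#'
#' Repression and dynamic range per genotype, computed by default from
#' replicate-mean expressions (ratio of means, matching triplicate
#' mean +/- SD reporting). With `per_replicate = TRUE` the ratio is instead
#' computed per replicate pair (wells matched by order within genotype and
#' condition) and then averaged - a sensitivity-check alternative that
#' requires equal replicate counts in the two conditions.
#'
#' @param expression data.frame from [process_plate()].
#' @param off_condition,on_condition Condition labels of the uninduced /
#'   induced state.
#' @param per_replicate Average per-replicate ratios instead of taking the
#'   ratio of means.
#' @return data.frame: `genotype`, `E_off`, `E_on`, `repression_pct`,
#'   `fold`.
#' @export
reporter_activity <- function(expression, off_condition = "-IPTG",
                              on_condition = "+IPTG",
                              per_replicate = FALSE) {
  wells <- attr(expression, "wells")
  if (per_replicate && is.null(wells)) {
    stop("per-replicate estimation needs the per-well values attached by ",
         "process_plate()")
  }
  gts <- unique(expression$genotype)
  rows <- lapply(gts, function(g) {
    off <- expression$mean[expression$genotype == g &
                             expression$condition == off_condition]
    on <- expression$mean[expression$genotype == g &
                            expression$condition == on_condition]
    if (!length(off) || !length(on)) return(NULL)
    if (per_replicate) {
      woff <- wells$expression[wells$genotype == g &
                                 wells$condition == off_condition]
      won <- wells$expression[wells$genotype == g &
                                wells$condition == on_condition]
      if (length(woff) != length(won)) {
        stop("per-replicate estimation needs equal replicate counts (",
             g, ")")
      }
      frac <- mean(repression(woff, won)$fraction)
      data.frame(genotype = g, E_off = off, E_on = on,
                 repression_pct = 100 * frac,
                 fold = mean(fold_change(woff, won)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(genotype = g, E_off = off, E_on = on,
                 repression_pct = repression(off, on)$percent,
                 fold = fold_change(off, on), stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write / read a plate table as CSV
#'
#' @param plate data.frame with `well`, `genotype`, `condition`, `od600`,
#'   `fluorescence`.
#' @param path File path.
#' @return `path` invisibly (write); the data.frame (read).
#' @export
write_plate_csv <- function(plate, path) {
  write.csv(plate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
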