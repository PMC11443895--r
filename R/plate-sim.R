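#' Simulate a plate-reader fluorometry table
#'
#' Emulates bulk fluorometry acquisition: each measured well reports
#' `F_raw = (signal + autofluorescence) * A_corr + F_bg + noise` and
#' `A_raw = A_corr + A_bg`, where `A_corr` is the corrected (biomass)
#' absorbance of the culture. Medium-only blank wells (`A_corr = 0`,
#' signal 0) and non-transformed wells (signal 0) are included so that
#' [process_plate()] can invert the acquisition; at `noise_sd = 0` the
#' inversion is exact.
#'
#' @param true_expression data.frame with columns `genotype`, `condition`,
#'   `signal` (true per-biomass expression, nonnegative; use genotype
#'   `"nontransformed"` rows only if you want to override its default 0).
#' @param noise_sd SD of additive Gaussian noise on raw fluorescence.
#' @param n_replicates Wells per genotype x condition.
#' @param F_bg,A_bg Medium background fluorescence and absorbance.
#' @param F_auto Autofluorescence of cells (per-biomass units).
#' @param A_corr Corrected absorbance of grown cultures (recycled across
#'   wells).
#' @param seed Integer seed.
#' @return data.frame: `well`, `genotype`, `condition`, `od600`,
#'   `fluorescence`.
#' @export
gen_plate <- function(true_expression, noise_sd = 0, n_replicates = 3,
                      F_bg = 100, A_bg = 0.05, F_auto = 200, A_corr = 0.5,
                      seed = 1) {
  stopifnot(is.data.frame(true_expression),
            all(c("genotype", "condition", "signal") %in%
                  names(true_expression)))
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (any(true_expression$signal < 0)) stop("signals must be nonnegative")
  set.seed(seed)
  spec <- true_expression
  if (!"nontransformed" %in% spec$genotype) {
    spec <- rbind(spec, data.frame(genotype = "nontransformed",
                                   condition = unique(spec$condition)[1],
                                   signal = 0))
  }
  rows <- list()
  for (i in seq_len(nrow(spec))) {
    for (r in seq_len(n_replicates)) {
      a_corr <- if (length(A_corr) > 1) A_corr[(r - 1) %% length(A_corr) + 1]
                else A_corr
      rows[[length(rows) + 1]] <- data.frame(
        genotype = spec$genotype[i], condition = spec$condition[i],
        od600 = a_corr + A_bg,
        fluorescence = (spec$signal[i] + F_auto) * a_corr + F_bg +
          if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0,
        stringsAsFactors = FALSE)
    }
  }
  # medium-only blanks
  for (r in seq_len(n_replicates)) {
    rows[[length(rows) + 1]] <- data.frame(
      genotype = "blank", condition = "none", od600 = A_bg,
      fluorescence = F_bg + if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- cbind(well = sprintf("%s%02d", LETTERS[(seq_len(nrow(out)) - 1) %/%
                                                  12 + 1],
                              (seq_len(nrow(out)) - 1) %% 12 + 1), out)
  out
}
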