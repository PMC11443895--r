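#' Derive a reproducible child seed for a pipeline stage
#'
#' One global seed is expanded into per-stage child seeds by a fixed integer
#' recurrence, so any stage can be regenerated independently of the others
#' while the whole run stays a pure function of the global seed.
#'
#' @param seed Global integer seed.
#' @param stage Character stage label (e.g. `"counts"`, `"plate"`).
#' @return An integer in `[1, 2^31 - 2]`, deterministic in `(seed, stage)`.
#' @examples
#' derive_seed(1, "counts")
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # modulus is a prime below 2^31 so the result is always a valid R integer
  m <- 2147483587
  as.integer(((abs(seed) %% m) * 48271 + h) %% m) + 1L
}
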