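#' Construct a paired RNA-seq/Ribo-seq count experiment
#'
#' @param rna,ribo Nonnegative integer matrices, genes x samples, with
#'   identical rownames (gene ids). `ribo` may be `NULL` for RNA-only
#'   experiments.
#' @param condition Character vector, one of `"control"`/`"MSI"` per sample
#'   column (same design for both assays).
#' @return Object of class `"count_experiment"`.
#' @export
count_experiment <- function(rna, ribo = NULL, condition) {
  check_counts <- function(m, what) {
    stopifnot(is.matrix(m), !is.null(rownames(m)))
    if (any(m < 0)) stop(what, " counts contain negative entries")
    if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", what)
  }
  check_counts(rna, "RNA")
  stopifnot(length(condition) == ncol(rna),
            all(condition %in% c("control", "MSI")))
  if (!is.null(ribo)) {
    check_counts(ribo, "Ribo")
    stopifnot(identical(rownames(rna), rownames(ribo)),
              ncol(ribo) == ncol(rna))
  }
  structure(list(rna = rna, ribo = ribo, condition = condition,
                 genes = rownames(rna)),
            class = "count_experiment")
}

#' @export
print.count_experiment <- function(x, ...) {
  cat("count_experiment:", nrow(x$rna), "genes,",
      ncol(x$rna), "samples per assay,",
      if (is.null(x$ribo)) "RNA only" else "RNA + Ribo", "\n")
  invisible(x)
}

#' Simulation configuration for synthetic count experiments
#'
#' Defaults mirror the study design this package models: two conditions
#' (void-plasmid control vs MSI-1* expression), two replicates each,
#' log-normal baseline expression and a common negative-binomial dispersion.
#'
#' @param n_genes Number of genes.
#' @param samples_per_condition Replicates per condition per assay.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   mean expression.
#' @param dispersion NB dispersion alpha >= 0 (variance mu + alpha mu^2);
#'   0 degenerates to Poisson.
#' @param size_factor_range Uniform range for per-sample size factors
#'   (drawn independently for RNA and Ribo samples).
#' @param tau_sdlog Log-normal sd of the per-gene baseline translation
#'   factor relating Ribo to RNA means.
#' @param seed Integer seed.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000, samples_per_condition = 2,
                       baseline_meanlog = log(300), baseline_sdlog = 1,
                       dispersion = 0.05, size_factor_range = c(0.8, 1.2),
                       tau_sdlog = 0.3, seed = 1) {
  stopifnot(n_genes >= 1, samples_per_condition >= 1, dispersion >= 0,
            length(size_factor_range) == 2, all(size_factor_range > 0),
            size_factor_range[1] <= size_factor_range[2])
  structure(list(n_genes = n_genes,
                 samples_per_condition = samples_per_condition,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion,
                 size_factor_range = size_factor_range,
                 tau_sdlog = tau_sdlog, seed = seed),
            class = "sim_config")
}

#' Simulation ground truth
#'
#' Records the planted effects a simulated experiment carries, so parameter
#' recovery can be checked downstream. Transcriptional and translational
#' effects are recorded independently (a gene may carry both).
#'
#' @param de Named numeric vector: gene id to planted transcriptional log2
#'   fold change (MSI vs control).
#' @param te Named numeric vector: gene id to planted translation-efficiency
#'   log2 shift.
#' @param motif_truth Optional per-TU planted-motif table (from
#'   [gen_transcriptome()]).
#' @param mutation_events Optional data.frame of evolution loss events (from
#'   [gen_evolution()]).
#' @return List of class `"sim_truth"`.
#' @export
sim_truth <- function(de = numeric(), te = numeric(), motif_truth = list(),
                      mutation_events = NULL) {
  structure(list(de = de, te = te, motif_truth = motif_truth,
                 mutation_events = mutation_events),
            class = "sim_truth")
}

#' Generate a synthetic paired RNA-seq/Ribo-seq count experiment
#'
#' RNA counts are NB with mean `sf_j * mu_i * 2^(de_i * x_j)` and Ribo counts
#' NB with mean `sf'_j * mu_i * tau_i * 2^((de_i + te_i) * x_j)`, where
#' `x_j` is the condition indicator (0 control, 1 MSI), `mu_i` the log-normal
#' baseline, `tau_i` a per-gene baseline translation factor and `sf` sample
#' size factors. With `dispersion = 0` counts are Poisson.
#'
#' @param config A [sim_config()].
#' @param truth A [sim_truth()]; gene names must be among
#'   `sprintf("g%04d", 1:n_genes)` (others are an error).
#' @return List with `experiment` (a [count_experiment()]) and `params`
#'   (per-gene `mu`, `tau`; per-sample size factors) for diagnostics.
#' @export
gen_counts <- function(config, truth = sim_truth()) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("g%04d", seq_len(ng))
  bad <- setdiff(c(names(truth$de), names(truth$te)), genes)
  if (length(bad)) stop("truth refers to unknown gene(s): ",
                        paste(bad, collapse = ", "))
  de <- te <- setNames(numeric(ng), genes)
  de[names(truth$de)] <- truth$de
  te[names(truth$te)] <- truth$te
  nrep <- config$samples_per_condition
  cond <- rep(c("control", "MSI"), each = nrep)
  x <- as.numeric(cond == "MSI")
  mu <- rlnorm(ng, config$baseline_meanlog, config$baseline_sdlog)
  tau <- rlnorm(ng, 0, config$tau_sdlog)
  sf_rna <- runif(2 * nrep, config$size_factor_range[1],
                  config$size_factor_range[2])
  sf_ribo <- runif(2 * nrep, config$size_factor_range[1],
                   config$size_factor_range[2])
  draw <- function(mean_mat) {
    cnt <- if (config$dispersion > 0) {
      rnbinom(length(mean_mat), mu = mean_mat, size = 1 / config$dispersion)
    } else {
      rpois(length(mean_mat), mean_mat)
    }
    m <- matrix(cnt, nrow = ng)
    storage.mode(m) <- "integer"
    m
  }
  rna_mean <- outer(seq_len(ng), seq_len(2 * nrep), function(i, j)
    sf_rna[j] * mu[i] * 2^(de[i] * x[j]))
  ribo_mean <- outer(seq_len(ng), seq_len(2 * nrep), function(i, j)
    sf_ribo[j] * mu[i] * tau[i] * 2^((de[i] + te[i]) * x[j]))
  rna <- draw(rna_mean)
  ribo <- draw(ribo_mean)
  dimnames(rna) <- list(genes, paste0("rna_", cond, "_", rep(1:nrep, 2)))
  dimnames(ribo) <- list(genes, paste0("ribo_", cond, "_", rep(1:nrep, 2)))
  list(experiment = count_experiment(rna, ribo, cond),
       params = list(mu = setNames(mu, genes), tau = setNames(tau, genes),
                     sf_rna = sf_rna, sf_ribo = sf_ribo))
}

#' Write / read a gene x sample count matrix as TSV
#'
#' First column `gene`, header row of sample ids.
#'
#' @param counts Integer matrix with rownames.
#' @param path File path.
#' @return `path` invisibly (write); the matrix (read).
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
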