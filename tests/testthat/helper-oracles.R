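# Independent oracles used to cross-check the implementation. These are
# deliberately naive (brute force / closed form) and share no code with R/.

# Benjamini-Hochberg step-up from its definition:
# adj_(k) = min_{j >= k} m * p_(j) / j, capped at 1, mapped back to input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (k in seq_len(m)) {
    adj[k] <- min(1, min(m * ps[k:m] / (k:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# hypergeometric upper tail by explicit summation of binomial coefficients
oracle_hyper_p <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# exhaustive sliding-window scan of the six concrete consensus strings
oracle_scan <- function(s) {
  pats <- c("AUAGU", "GUAGU", "AUUAGU", "GUUAGU", "AUUUAGU", "GUUUAGU")
  hits <- NULL
  for (p in pats) {
    L <- nchar(p)
    if (nchar(s) < L) next
    for (o in 0:(nchar(s) - L)) {
      if (substr(s, o + 1, o + L) == p) {
        hits <- rbind(hits, data.frame(offset = o, pattern = p))
      }
    }
  }
  if (is.null(hits)) return(data.frame(offset = integer(),
                                       pattern = character()))
  hits[order(hits$offset), , drop = FALSE]
}

random_rna <- function(len, gc_rich = FALSE) {
  prob <- if (gc_rich) c(.15, .35, .35, .15) else rep(.25, 4)
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE, prob = prob),
        collapse = "")
}

# small deterministic count experiment with planted effects, for recovery
# tests; all baselines equal so power is uniform
make_te_experiment <- function(n_genes = 200, mu = 500, dispersion = 0.05,
                               te = c(g0001 = 2), de = numeric(),
                               nrep = 2, seed = 1) {
  cfg <- sim_config(n_genes = n_genes, samples_per_condition = nrep,
                    baseline_meanlog = log(mu), baseline_sdlog = 0,
                    dispersion = dispersion, tau_sdlog = 0, seed = seed)
  gen_counts(cfg, sim_truth(de = de, te = te))$experiment
}
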