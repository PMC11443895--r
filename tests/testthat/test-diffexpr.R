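test_that("size factors match the median-of-ratios definition", {
  m <- matrix(c(10L, 30L, 100L, 20L, 60L, 200L), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  # sample b = 2 x sample a: factors (1/sqrt(2), sqrt(2))
  expect_equal(estimate_size_factors(m), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # identical samples -> (1, 1)
  m2 <- cbind(a = c(5L, 7L, 9L), b = c(5L, 7L, 9L))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(estimate_size_factors(m2), c(1, 1))
  # permutation invariance over genes
  set.seed(1)
  m3 <- matrix(rnbinom(300, mu = 100, size = 10), ncol = 3)
  rownames(m3) <- paste0("g", 1:100)
  expect_equal(estimate_size_factors(m3),
               estimate_size_factors(m3[sample(100), ]))
  expect_error(estimate_size_factors(matrix(c(0L, 1L, 1L, 0L), 2,
                                            dimnames = list(c("a", "b"), NULL))),
               "degenerate")
})

test_that("size factors agree with DESeq2's median-of-ratios", {
  skip_if_not_installed("DESeq2")
  set.seed(2)
  m <- matrix(rnbinom(2000, mu = 200, size = 5), ncol = 4)
  rownames(m) <- sprintf("g%03d", 1:500)
  expect_equal(estimate_size_factors(m),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("dispersion estimation recovers truth and clamps degeneracies", {
  set.seed(3)
  cond <- rep(c("a", "b"), each = 50)
  # NB truth alpha = 0.2 at mu = 500, n = 50+50: MoM lands in [0.1, 0.3]
  m <- matrix(rnbinom(500 * 100, mu = 500, size = 1 / 0.2), ncol = 100)
  rownames(m) <- sprintf("g%03d", 1:500)
  a <- estimate_dispersion(m, rep(1, 100), cond, mode = "per-gene")
  expect_gt(median(a), 0.1)
  expect_lt(median(a), 0.3)
  # Poisson truth: per-gene estimates concentrate near zero
  mp <- matrix(rpois(500 * 100, 500), ncol = 100)
  rownames(mp) <- sprintf("g%03d", 1:500)
  ap <- estimate_dispersion(mp, rep(1, 100), cond, mode = "per-gene")
  expect_lt(median(ap), 0.01)
  # constant counts: variance below mean clamps at zero
  mc <- matrix(100L, nrow = 2, ncol = 4,
               dimnames = list(c("g1", "g2"), NULL))
  expect_equal(unname(estimate_dispersion(mc, rep(1, 4), c("a", "a", "b", "b"),
                                          mode = "per-gene")), c(0, 0),
               ignore_attr = TRUE)
  # all-zero gene is flagged untestable
  mz <- rbind(g1 = c(5L, 6L, 7L, 8L), g2 = c(0L, 0L, 0L, 0L))
  az <- estimate_dispersion(mz, rep(1, 4), c("a", "a", "b", "b"))
  expect_true(is.na(az["g2"]))
})

test_that("bh_adjust equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.05), 0.05)
  set.seed(4)
  for (i in 1:100) {
    p <- runif(sample(1:60, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the call rule applies both the significance and fold cutoffs", {
  expect_equal(classify_de(0.04, log2(1.6)), "up")
  expect_equal(classify_de(0.04, log2(1.4)), "ns")
  expect_equal(classify_de(0.06, 2), "ns")
  expect_equal(classify_de(0.04, -log2(1.6)), "down")
  expect_equal(classify_de(NA, 3), "ns")
})

test_that("wald_test computes exact fold changes on clean inputs", {
  m <- rbind(gA = c(100L, 100L, 400L, 400L), gB = c(50L, 50L, 50L, 50L))
  cond <- c("control", "control", "MSI", "MSI")
  res <- wald_test(m, size_factors = rep(1, 4),
                   dispersions = c(0.05, 0.05), condition = cond)
  expect_equal(res$log2fc[res$gene == "gA"], 2)
  expect_equal(res$log2fc[res$gene == "gB"], 0)
  expect_equal(res$p[res$gene == "gB"], 1)
  expect_true(all(res$padj >= res$p, na.rm = TRUE))
})

test_that("swapping condition labels negates every log2 fold change", {
  expt <- make_te_experiment(n_genes = 100, de = c(g0005 = 1.5), seed = 5)
  a <- wald_test(expt$rna, condition = expt$condition, ref = "control")
  b <- wald_test(expt$rna, condition = expt$condition, ref = "MSI")
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p, b$p)
})

test_that("fold changes are invariant under global count rescaling", {
  # the median-of-ratios reference rescales with the counts, so the factors
  # themselves are unchanged and every fold change is preserved exactly
  expt <- make_te_experiment(n_genes = 100, de = c(g0003 = 1), seed = 6)
  m <- expt$rna
  expect_equal(estimate_size_factors(m * 3L), estimate_size_factors(m),
               tolerance = 1e-12)
  r1 <- wald_test(m, dispersions = rep(0.05, 100),
                  condition = expt$condition)
  r2 <- wald_test(m * 3L, dispersions = rep(0.05, 100),
                  condition = expt$condition)
  expect_equal(r1$log2fc, r2$log2fc, tolerance = 1e-12)
})

test_that("low-count genes are excluded from testing and the BH family", {
  m <- rbind(gA = c(100L, 120L, 90L, 110L), gB = c(1L, 0L, 2L, 0L))
  res <- wald_test(m, condition = c("control", "control", "MSI", "MSI"),
                   dispersions = c(0.05, 0.05), size_factors = rep(1, 4))
  expect_equal(res$call[res$gene == "gB"], "low_count")
  expect_true(is.na(res$p[res$gene == "gB"]))
})

test_that("type-I error of the Wald test is near nominal at known dispersion", {
  set.seed(20)
  m <- matrix(rnbinom(2000 * 4, mu = 500, size = 1 / 0.05), ncol = 4)
  rownames(m) <- sprintf("g%04d", 1:2000)
  res <- wald_test(m, dispersions = rep(0.05, 2000),
                   condition = c("control", "control", "MSI", "MSI"))
  rate <- mean(res$p < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("empirical FDR of DE calls stays near the nominal level", {
  # 10% planted effects; estimated (moderated) dispersions; the FDR among
  # up/down calls should not exceed ~1.5x nominal across repetitions
  fdrs <- vapply(1:5, function(s) {
    cfg <- sim_config(n_genes = 1000, baseline_meanlog = log(300),
                      baseline_sdlog = 1, dispersion = 0.05, seed = 100 + s)
    genes <- sprintf("g%04d", 1:1000)
    de <- setNames(rep(c(2, -2), 50), sample(genes, 100))
    sim <- gen_counts(cfg, sim_truth(de = de))
    res <- wald_test(sim$experiment$rna, condition = sim$experiment$condition)
    called <- res$gene[res$call %in% c("up", "down")]
    if (!length(called)) return(0)
    mean(!called %in% names(de))
  }, 0)
  expect_lte(mean(fdrs), 1.5 * 0.05)
})

test_that("te_test isolates translational from transcriptional regulation", {
  # one planted TE gene and one DE-only gene: only the former is TE-called
  expt <- make_te_experiment(n_genes = 300, te = c(g0010 = 2),
                             de = c(g0020 = 2), nrep = 3, seed = 7)
  res <- te_test(expt)
  expect_equal(res$call[res$gene == "g0010"], "up")
  expect_equal(res$call[res$gene == "g0020"], "ns")
  expect_gt(res$delta_te[res$gene == "g0010"], 1)
  expect_lt(abs(res$delta_te[res$gene == "g0020"]), 1)
})

test_that("te_test gives zero TE change when Ribo equals RNA", {
  expt <- make_te_experiment(n_genes = 50, seed = 8)
  expt$ribo <- expt$rna
  colnames(expt$ribo) <- sub("rna", "ribo", colnames(expt$rna))
  res <- te_test(expt)
  expect_equal(res$delta_te, rep(0, 50))
  expect_true(all(res$call %in% c("ns", "low_count")))
  rna_only <- count_experiment(expt$rna, condition = expt$condition)
  expect_error(te_test(rna_only), "Ribo assay missing")
})

test_that("te_test detects a planted 4-fold TE shift with high power", {
  hits <- vapply(1:40, function(s) {
    expt <- make_te_experiment(n_genes = 200, te = c(g0001 = 2), seed = 300 + s)
    res <- te_test(expt)
    res$p[res$gene == "g0001"] < 0.05 && res$delta_te[res$gene == "g0001"] > 0
  }, TRUE)
  expect_gt(mean(hits), 0.9)
})

test_that("count_experiment validates its invariants", {
  m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), NULL))
  expect_error(count_experiment(m - 2L, condition = c("control", "MSI")),
               "negative")
  bad <- matrix(1:4, 2, dimnames = list(c("g1", "g1"), NULL))
  expect_error(count_experiment(bad, condition = c("control", "MSI")),
               "duplicate")
})
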