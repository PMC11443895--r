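test_that("gen_transcriptome plants exactly the planned motifs", {
  plan <- c(TU0001 = 2L, TU0003 = 3L)
  txp <- gen_transcriptome(4, motif_plan = plan, seed = 1)
  sc <- scan_transcriptome(txp$tus)
  expect_equal(sc$report$count,
               c(2L, 0L, 3L, 0L))
  # recorded offsets are exactly what the scanner finds
  for (id in names(plan)) {
    expect_setequal(sc$hits$offset[sc$hits$tu_id == id],
                    txp$truth[[id]]$offset)
  }
  # all-zero plan -> genome-wide zero
  txp0 <- gen_transcriptome(5, seed = 2)
  expect_equal(sum(scan_transcriptome(txp0$tus)$report$count), 0L)
})

test_that("gen_transcriptome is byte-deterministic and validates plans", {
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_tu_fasta(gen_transcriptome(3, motif_plan = c(TU0002 = 1), seed = 7)$tus, f1)
  write_tu_fasta(gen_transcriptome(3, motif_plan = c(TU0002 = 1), seed = 7)$tus, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(gen_transcriptome(2, motif_plan = c(TU0009 = 1), seed = 1),
               "not in TU set")
  # infeasible plan: more motifs than the sequence can hold
  expect_error(
    gen_transcriptome(1, genes_per_tu = 1, motif_plan = c(TU0001 = 50),
                      seed = 1, utr_len = 5:6, cds_codons = 10:12),
    "infeasible")
})

test_that("TU features are well-formed 5'UTR/CDS(/3'UTR) blocks", {
  txp <- gen_transcriptome(5, seed = 11)
  for (t in txp$tus) {
    expect_true(all(t$features$end <= nchar(t$sequence)))
    expect_true(all(t$features$start < t$features$end))
    expect_true(all(c("5'UTR", "CDS") %in% t$features$region))
    cds <- t$features[t$features$region == "CDS", ]
    expect_true(all((cds$end - cds$start) %% 3 == 0))
  }
})

test_that("FASTA/GFF3 round trip preserves sequences and features", {
  txp <- gen_transcriptome(4, motif_plan = c(TU0001 = 2), seed = 5)
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_tu_fasta(txp$tus, fa)
  write_tu_gff3(txp$tus, gff)
  back <- read_tu_set(fa, gff)
  expect_equal(names(back), names(txp$tus))
  for (id in names(back)) {
    expect_equal(back[[id]]$sequence, txp$tus[[id]]$sequence)
    a <- back[[id]]$features[order(back[[id]]$features$start,
                                   back[[id]]$features$region), ]
    b <- txp$tus[[id]]$features[order(txp$tus[[id]]$features$start,
                                      txp$tus[[id]]$features$region), ]
    expect_equal(a$start, b$start)
    expect_equal(a$end, b$end)
    expect_equal(a$region, b$region)
    expect_equal(a$gene_id, b$gene_id)
  }
})

test_that("gen_counts hits its planted means and dispersion", {
  # planted transcriptional doubling: empirical MSI/control ratio -> 2
  cfg <- sim_config(n_genes = 5000, baseline_meanlog = log(500),
                    baseline_sdlog = 0, dispersion = 0.05,
                    size_factor_range = c(1, 1), seed = 3)
  de <- setNames(rep(1, 5000), sprintf("g%04d", 1:5000))
  sim <- gen_counts(cfg, sim_truth(de = de))
  rna <- sim$experiment$rna
  ratio <- mean(rna[, 3:4]) / mean(rna[, 1:2])
  expect_lt(abs(ratio - 2), 0.05)
  # TE-only effect: RNA ratio ~ 1, Ribo ratio ~ 2
  te <- setNames(rep(1, 5000), sprintf("g%04d", 1:5000))
  sim2 <- gen_counts(cfg, sim_truth(te = te))
  expect_lt(abs(mean(sim2$experiment$rna[, 3:4]) /
                  mean(sim2$experiment$rna[, 1:2]) - 1), 0.03)
  expect_lt(abs(mean(sim2$experiment$ribo[, 3:4]) /
                  mean(sim2$experiment$ribo[, 1:2]) - 2), 0.06)
  # NB variance/mean matches 1 + alpha * mu at fixed mu
  vm <- var(as.vector(rna[, 1:2])) / mean(rna[, 1:2])
  expect_gt(vm, 1)
  expect_lt(abs(vm - (1 + 0.05 * 500)) / (1 + 0.05 * 500), 0.15)
})

test_that("zero dispersion degenerates to Poisson and seeds reproduce", {
  cfg <- sim_config(n_genes = 3000, baseline_meanlog = log(400),
                    baseline_sdlog = 0, dispersion = 0,
                    size_factor_range = c(1, 1), tau_sdlog = 0, seed = 8)
  sim <- gen_counts(cfg)
  rna <- sim$experiment$rna
  # Poisson: variance/mean ~ 1, conditions indistinguishable
  expect_lt(abs(var(as.vector(rna)) / mean(rna) - 1), 0.1)
  expect_lt(abs(mean(rna[, 3:4]) / mean(rna[, 1:2]) - 1), 0.03)
  sim2 <- gen_counts(cfg)
  expect_identical(sim$experiment$rna, sim2$experiment$rna)
  expect_identical(sim$experiment$ribo, sim2$experiment$ribo)
})

test_that("count TSV and plate CSV round-trip", {
  cfg <- sim_config(n_genes = 20, seed = 4)
  m <- gen_counts(cfg)$experiment$rna
  p <- tempfile(fileext = ".tsv")
  write_counts_tsv(m, p)
  expect_identical(read_counts_tsv(p), m)

  plate <- gen_plate(data.frame(genotype = "WT", condition = c("-IPTG", "+IPTG"),
                                signal = c(1000, 100)), noise_sd = 1, seed = 2)
  pc <- tempfile(fileext = ".csv")
  write_plate_csv(plate, pc)
  back <- read_plate_csv(pc)
  expect_equal(back$fluorescence, plate$fluorescence, tolerance = 1e-12)
  expect_equal(back$genotype, plate$genotype)
})

test_that("gen_plate inverts exactly at zero noise and honestly with noise", {
  spec <- data.frame(genotype = c("WT", "WT", "mut", "mut"),
                     condition = rep(c("-IPTG", "+IPTG"), 2),
                     signal = c(1000, 108, 1000, 900))
  plate <- gen_plate(spec, noise_sd = 0, seed = 1)
  expr <- process_plate(plate)
  for (i in seq_len(nrow(spec))) {
    got <- expr$mean[expr$genotype == spec$genotype[i] &
                       expr$condition == spec$condition[i]]
    expect_equal(got, spec$signal[i], tolerance = 1e-9)
  }
  act <- reporter_activity(expr)
  expect_equal(act$repression_pct[act$genotype == "WT"], 89.2,
               tolerance = 1e-9)
  # with noise: replicate spread is positive, mean converges with replicates
  noisy <- gen_plate(spec[1:2, ], noise_sd = 20, n_replicates = 200, seed = 9)
  e2 <- process_plate(noisy)
  expect_true(all(e2$sd > 0))
  expect_lt(abs(e2$mean[e2$condition == "-IPTG"] - 1000), 15)
  expect_error(gen_plate(spec, noise_sd = -1), "nonnegative")
})

test_that("non-transformed wells recover zero expression", {
  spec <- data.frame(genotype = c("WT", "nontransformed"),
                     condition = "-IPTG", signal = c(500, 0))
  plate <- gen_plate(spec, noise_sd = 0, seed = 1)
  blanks <- plate$genotype == "blank"
  F_bg <- mean(plate$fluorescence[blanks]); A_bg <- mean(plate$od600[blanks])
  auto <- plate$genotype == "nontransformed"
  norm <- normalized_fluorescence(plate$fluorescence[auto],
                                  plate$od600[auto], F_bg, A_bg)
  F_auto <- mean(norm)
  expect_equal(norm - F_auto, rep(0, sum(auto)), tolerance = 1e-9)
})

test_that("gen_evolution honors its probability model", {
  # no mutation: flat trajectories, no loss call on any line
  g0 <- gen_evolution(n_lines = 10, mutation_prob = c(reporter = 0),
                      seed = 1)
  expect_equal(nrow(g0$truth), 0L)
  expect_true(all(g0$lines$dr == 10))
  s0 <- summarize_lines(g0$lines)
  expect_equal(s0$arms$surviving_fraction, 1)
  # certain mutation: every line loses on day 1, visible from day 1 + lag
  g1 <- gen_evolution(n_lines = 6, mutation_prob = c(reporter = 1),
                      lag = 1, seed = 2)
  expect_equal(g1$truth$day, rep(1L, 6))
  expect_true(all(g1$lines$dr[2, ] == 1))
  # event fraction matches the geometric closed form
  g <- gen_evolution(n_lines = 1000, days = 7,
                     mutation_prob = c(reporter = 0.3), seed = 5)
  expect_lt(abs(nrow(g$truth) / 1000 - (1 - 0.7^7)), 0.03)
})

test_that("detect_loss recovers planted event days within the takeover lag", {
  g <- gen_evolution(n_lines = 50, days = 10,
                     mutation_prob = c(reporter = 0.3), lag = 1, seed = 6)
  for (i in seq_len(nrow(g$truth))) {
    ev <- detect_loss(g$lines$dr[, g$truth$line_id[i]], threshold = 2,
                      persistence = 2, bottleneck = 0.01)
    if (g$truth$day[i] + 1 <= 9) {   # detectable within the window
      expect_false(is.null(ev))
      expect_gte(ev$day, g$truth$day[i])
      expect_lte(ev$day, g$truth$day[i] + 1)
    }
  }
})

test_that("derived child seeds are deterministic and stage-distinct", {
  expect_identical(derive_seed(1, "counts"), derive_seed(1, "counts"))
  expect_false(derive_seed(1, "counts") == derive_seed(1, "plate"))
  expect_false(derive_seed(1, "counts") == derive_seed(2, "counts"))
  s <- vapply(1:1000, derive_seed, 1L, stage = "x")
  expect_true(all(s >= 1 & s <= 2^31 - 1))
})
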