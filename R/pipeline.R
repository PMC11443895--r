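#' Published repression percentages of MSI-1* variants
#'
#' Repression of the two-motif sfGFP reporter upon IPTG induction, as
#' characterized by bulk fluorometry for the original regulator and the
#' RRM1 point mutants with reported values. Useful as reference inputs for
#' reporter-model examples: expression ratios can be reconstructed by
#' inverting the percentage.
#'
#' @return data.frame with `variant` and `repression_pct`.
#' @export
msi_variant_repression <- function() {
  data.frame(
    variant = c("WT", "R53E", "R99A", "L50P", "R61E"),
    repression_pct = c(89.2, 91.7, 86.2, 65.8, 46.5),
    stringsAsFactors = FALSE)
}

#' Configuration for an end-to-end synthetic run
#'
#' Defaults define the study conditions the package emulates: a
#' transcriptome of polycistronic TUs with a handful of motif-bearing
#' mRNAs, duplicate RNA-seq/Ribo-seq libraries per condition, ~10% of genes
#' with transcriptional effects and exactly two genes with strong
#' translation-efficiency shifts, one inside a duplicate-motif TU (a direct
#' target) and one inside a single-motif TU (an indirect responder).
#'
#' @param outdir Output directory for stage files and the manifest.
#' @param seed Global seed; every random stage gets a derived child seed.
#' @param n_tus Number of transcriptional units.
#' @param n_duplicate_tus,n_single_tus TUs planted with 2 / 1 consensus
#'   occurrences (the rest carry none).
#' @param samples_per_condition Replicates per condition per assay.
#' @param dispersion NB dispersion.
#' @param de_fraction Fraction of genes with a planted transcriptional
#'   effect (half up at `+de_effect`, half down at `-de_effect`).
#' @param de_effect,te_effect Planted log2 effect sizes.
#' @param alpha,min_fold,min_count Testing parameters.
#' @param require_duplicate Motif criterion for direct-target calls.
#' @param n_terms,term_size Random term-map geometry for the enrichment
#'   stage (one extra term collects planted up-regulated genes).
#' @param bottleneck,evo_days,loss_threshold,loss_persistence Evolution
#'   stage parameters.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(outdir = tempfile("msikit_run_"), seed = 1,
                       n_tus = 120, n_duplicate_tus = 5, n_single_tus = 10,
                       samples_per_condition = 2, dispersion = 0.05,
                       de_fraction = 0.1, de_effect = 2, te_effect = 3,
                       alpha = 0.05, min_fold = 1.5, min_count = 10,
                       require_duplicate = TRUE,
                       n_terms = 20, term_size = 15,
                       bottleneck = 0.01, evo_days = 7,
                       loss_threshold = 2, loss_persistence = 2) {
  stopifnot(n_duplicate_tus + n_single_tus <= n_tus)
  cfg <- mget(names(formals()))
  structure(cfg, class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Stages, in dependency order: simulate (transcriptome, counts, term map,
#' reporter plates, evolution lines) -> differential expression -> TE test
#' -> motif scan -> direct/indirect target calls -> enrichment -> reporter
#' activity -> evolution summary. Every stage's outputs are written under
#' `config$outdir` and checksummed into a JSON manifest; reruns with the
#' same configuration are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and
#'   `manifest` (path of the JSON manifest).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)

  ## -- simulate ----------------------------------------------------------
  plan <- c(rep(2L, config$n_duplicate_tus), rep(1L, config$n_single_tus))
  names(plan) <- sprintf("TU%04d", seq_along(plan))
  txp <- gen_transcriptome(config$n_tus, motif_plan = plan,
                           seed = derive_seed(config$seed, "transcriptome"))
  gene_to_tu <- do.call(c, unname(lapply(txp$tus, function(t)
    setNames(rep(t$tu_id, length(unique(t$features$gene_id))),
             unique(t$features$gene_id)))))
  genes <- sort(names(gene_to_tu))
  ng <- length(genes)

  # two TE genes: one in a duplicate-motif TU, one in a single-motif TU
  te_direct <- names(gene_to_tu)[gene_to_tu == "TU0001"][1]
  te_indirect <- names(gene_to_tu)[gene_to_tu ==
                                     sprintf("TU%04d",
                                             config$n_duplicate_tus + 1)][1]
  te <- setNames(c(config$te_effect, -config$te_effect),
                 c(te_direct, te_indirect))
  set.seed(derive_seed(config$seed, "truth"))
  n_de <- round(config$de_fraction * ng)
  de_genes <- sample(setdiff(genes, names(te)), n_de)
  de <- setNames(rep(c(config$de_effect, -config$de_effect),
                     length.out = n_de), de_genes)
  truth <- sim_truth(de = de, te = te, motif_truth = txp$truth)

  cfg_counts <- sim_config(
    n_genes = ng,
    samples_per_condition = config$samples_per_condition,
    dispersion = config$dispersion,
    seed = derive_seed(config$seed, "counts"))
  sim <- gen_counts(cfg_counts, truth)
  expt <- sim$experiment

  # term map: random terms over the universe plus one collecting planted
  # up-regulated genes (the enrichment stage should recover it)
  set.seed(derive_seed(config$seed, "terms"))
  term_map <- setNames(lapply(seq_len(config$n_terms), function(i)
    sample(genes, config$term_size)), sprintf("term%02d", 1:config$n_terms))
  up_genes <- names(de)[de > 0]
  term_map$planted_up_response <-
    unique(c(sample(up_genes, min(length(up_genes), config$term_size)),
             sample(genes, 3)))

  # reporter plates from the published variant repressions, zero noise
  ref <- msi_variant_repression()
  spec <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i)
    data.frame(genotype = ref$variant[i], condition = c("-IPTG", "+IPTG"),
               signal = c(1000, 1000 * (1 - ref$repression_pct[i] / 100)))))
  plate <- gen_plate(spec, noise_sd = 0,
                     seed = derive_seed(config$seed, "plate"))

  # evolution arms emulating the four experimental arms
  arms <- list(
    list(medium = "-IPTG", copy_class = "high",
         prob = c(reporter = 0.35, promoter = 0)),
    list(medium = "+IPTG", copy_class = "high",
         prob = c(reporter = 0.15, promoter = 0.25)),
    list(medium = "-IPTG", copy_class = "medium",
         prob = c(reporter = 0.35, promoter = 0)),
    list(medium = "+IPTG", copy_class = "medium",
         prob = c(reporter = 0.03, promoter = 0)))
  evo <- lapply(seq_along(arms), function(i) {
    gen_evolution(n_lines = 5, days = config$evo_days,
                  bottleneck = config$bottleneck,
                  mutation_prob = arms[[i]]$prob,
                  medium = arms[[i]]$medium,
                  copy_class = arms[[i]]$copy_class,
                  seed = derive_seed(config$seed, paste0("evolution", i)))
  })
  evo_all <- do.call(cbind, lapply(evo, function(e) e$lines$dr))
  evo_meta <- do.call(rbind, lapply(evo, function(e) e$lines$meta))
  evo_meta$line_id <- sprintf("line%02d", seq_len(nrow(evo_meta)))
  lines <- evolution_lines(evo_all, evo_meta,
                           passage_scheme(config$bottleneck, config$evo_days))

  write_tu_fasta(txp$tus, out("transcriptome.fasta"))
  write_tu_gff3(txp$tus, out("transcriptome.gff3"))
  write_counts_tsv(expt$rna, out("counts_rna.tsv"))
  write_counts_tsv(expt$ribo, out("counts_ribo.tsv"))
  write_plate_csv(plate, out("plate.csv"))
  write_trajectories_tsv(lines, out("trajectories.tsv"))
  jsonlite::write_json(
    list(de = as.list(truth$de), te = as.list(truth$te),
         motif_offsets = lapply(truth$motif_truth, function(m) m$offset)),
    out("truth.json"), auto_unbox = TRUE, digits = NA)

  ## -- analyse -----------------------------------------------------------
  de_res <- wald_test(expt$rna, condition = expt$condition,
                      alpha = config$alpha, min_fold = config$min_fold,
                      min_count = config$min_count)
  te_res <- te_test(expt, alpha = config$alpha, min_fold = config$min_fold,
                    min_count = config$min_count)
  scan <- scan_transcriptome(txp$tus)
  targets <- call_direct_targets(te_res, scan$report, gene_to_tu,
                                 require_duplicate = config$require_duplicate)
  enr <- enrich(de_res$gene[de_res$call == "up"], term_map, genes,
                alpha = config$alpha)
  expr <- process_plate(plate)
  activity <- reporter_activity(expr)
  evo_summary <- summarize_lines(lines, config$loss_threshold,
                                 config$loss_persistence)

  write_result_tsv(de_res, out("de.tsv"))
  write_result_tsv(te_res, out("te.tsv"))
  write_hits_bed(scan$hits, out("motif_hits.bed"))
  write_result_tsv(scan$report, out("motif_report.tsv"))
  write_result_tsv(targets, out("targets.tsv"))
  write_result_tsv(enr, out("enrichment.tsv"))
  write_result_tsv(activity, out("reporter_activity.tsv"))
  write_result_tsv(evo_summary$arms, out("evolution_arms.tsv"))

  ## -- manifest ----------------------------------------------------------
  files <- list.files(config$outdir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package = "msikit",
    version = as.character(utils::packageVersion("msikit")),
    seed = config$seed,
    child_seeds = list(
      transcriptome = derive_seed(config$seed, "transcriptome"),
      truth = derive_seed(config$seed, "truth"),
      counts = derive_seed(config$seed, "counts"),
      terms = derive_seed(config$seed, "terms"),
      plate = derive_seed(config$seed, "plate")),
    parameters = unclass(config)[setdiff(names(config), "outdir")],
    checksums = as.list(setNames(unname(tools::md5sum(files)),
                                 basename(files))))
  manifest_path <- out("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(truth = truth, experiment = expt, de = de_res, te = te_res,
                 scan = scan, targets = targets, enrichment = enr,
                 activity = activity, evolution = evo_summary,
                 lines = lines, gene_to_tu = gene_to_tu,
                 manifest = manifest_path))
}
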