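# msikit

Tools for characterizing a heterologous RNA-binding protein — a truncated
mouse Musashi-1 (MSI-1*) — used as a translational repressor in *Escherichia
coli*. The package covers the computational side of such a characterization
end to end, and ships a synthetic-data generator with recorded ground truth
so that every stage is testable without any external download.

## What it computes

**Differential expression and translation efficiency.** From paired
RNA-seq/Ribo-seq count matrices (two conditions: void plasmid vs MSI-1*),
counts are normalized with median-of-ratios size factors and modeled as
negative binomial with variance μ + αμ². Per gene, the log2 fold change of
condition means is tested with a Wald statistic (`log2fc / se`, normal
reference), BH-corrected, and called `up`/`down` when `padj < 0.05` and the
linear fold change exceeds 1.5×. Translation efficiency (TE) is Ribo-seq
signal normalized by RNA-seq signal; a TE change is the interaction contrast

```
ΔTE = log2FC(Ribo) − log2FC(RNA),   se = sqrt(se²_Ribo + se²_RNA)
```

tested and called the same way, so transcriptional effects cancel and only
translational regulation remains.

**Motif scanning.** Musashi binds the degenerate consensus `RUnAGU`
(R ∈ {A,G}, n = 1–3 uridines; six concrete patterns, 5–7 nt). Transcriptional
units (polycistronic mRNAs with 5'UTR/CDS/3'UTR features) are scanned on the
sense strand, overlapping occurrences included; a TU carrying the motif *in
duplicate* (≥ 2 occurrences, one per RRM of the protein) is a binding
candidate. TE-responsive genes are then classified `direct-candidate`
(motif-supported) vs `indirect` (burden effects).

**Enrichment.** One-sided Fisher exact (hypergeometric tail) tests of
up/down gene lists against a gene universe, BH-corrected.

**Reporter arithmetic.** Plate-reader fluorometry is reduced to expression
as `(F − F_bg)/(A − A_bg) − F_auto`; repression is `1 − E_on/E_off`, the
dynamic range `E_off/E_on`, and for a two-motif target the independent-binding
model predicts `fold_two = fold_RBS × fold_AUG`.

**Evolutionary stability.** Serial passage under a daily fraction-*b*
bottleneck gives `log2(1/b)` generations per day (6.64 for 1:100); loss of
regulatory function is detected from daily dynamic-range trajectories by a
threshold-persistence rule and reported in generations.

## Worked example

```r
library(msikit)

# transcriptome with known planted motifs
txp <- gen_transcriptome(20, motif_plan = c(TU0001 = 2, TU0002 = 1), seed = 1)
sc  <- scan_transcriptome(txp$tus)
subset(sc$report, count > 0)
#>    tu_id count duplicate             regions
#> 1 TU0001     2      TRUE CDS:g0001,CDS:g0001
#> 2 TU0002     1     FALSE           CDS:g0003

# paired counts with one planted 8-fold TE shift (gene g0007)
cfg <- sim_config(n_genes = 500, dispersion = 0.05, seed = 2)
sim <- gen_counts(cfg, sim_truth(te = c(g0007 = 3)))
te  <- te_test(sim$experiment)
te[te$call %in% c("up", "down"),
   c("gene", "log2fc_rna", "log2fc_ribo", "delta_te", "padj", "call")]
#>      gene log2fc_rna log2fc_ribo  delta_te         padj call
#> 7   g0007 -0.1433494   2.9269414  3.070291 1.832848e-08   up
#> 145 g0145  1.1721361  -0.5837671 -1.755903 4.717381e-02 down
```

The planted gene is recovered with a ΔTE estimate near its true value of 3;
g0145 is a borderline false call (padj = 0.047) of the kind an FDR-controlled
screen occasionally admits — at 2+2 replicates, calls near the cutoff should
be treated as candidates.

```r
r <- repression(1000, 108)
sprintf("%.1f%% repression, %.2f-fold dynamic range", r$percent,
        fold_change(1000, 108))
#> "89.2% repression, 9.26-fold dynamic range"

predict_two_motif_fc(3.1, 3.0)         # independent-binding prediction
#> 9.3

generations_per_day(0.01)              # 1:100 daily bottleneck
#> 6.643856
cumulative_generations(passage_scheme(0.01, 7))
#> 46.50699
detect_loss(c(10, 10, 10, 1.2, 1.1, 1.0, 1.0), threshold = 2)
#> $day
#> [1] 4
#> $generations
#> [1] 26.57542
```

`run_pipeline(run_config(outdir = "out", seed = 1))` runs everything —
simulation, DE/TE testing, motif scan, target calls, enrichment, reporter
reduction, evolution summary — writing TSV/FASTA/GFF3/CSV outputs and a JSON
manifest with derived per-stage seeds and file checksums; reruns with the
same seed are byte-identical.

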