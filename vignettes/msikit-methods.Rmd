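---
title: "Models and methods behind msikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind msikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msikit)
```

msikit analyzes a synthetic-biology system in which a truncated mouse
Musashi-1 protein (MSI-1*, two RNA-recognition motifs, no disordered
C-terminal tail) represses translation in *E. coli* by binding the consensus
RU~n~AGU (R a purine, n = 1–3 uridines) near a ribosome binding site. This
vignette explains the statistical models, the conventions, the tunable
parameters, and the choices made where the design was genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## Count model and differential expression

Counts are modeled as negative binomial with mean μ and dispersion α,
`var = μ + αμ²`; α = 0 degenerates to Poisson. This is the standard RNA-seq
parameterization and what the in-repo simulator draws from.

**Size factors.** `estimate_size_factors()` is the median-of-ratios
estimator: per sample, the median over genes (with positive geometric mean
across samples) of `count / geometric mean`. Doubling one sample's library
multiplies its factor accordingly; scaling *all* samples leaves the factors
unchanged because the reference scales with them — the invariant that
matters is that fold changes are preserved, which the tests check.

**Dispersion.** With two replicates per condition (the design this package
mirrors), per-gene moments are nearly uninformative (~2 degrees of freedom),
so `estimate_dispersion()` offers three policies:

* `per-gene`: method-of-moments on normalized counts, variance pooled
  *within* condition (so planted condition effects never inflate it),
  `α̂ = max(0, (s² − μ̄)/μ̄²)`. Accurate at high replication (the test suite
  recovers α = 0.2 within [0.1, 0.3] at n = 50 + 50) but extremely noisy at
  n = 2 + 2.
* `pooled`: a single common value, the ratio of sums
  `Σᵢ(s²ᵢ − μ̄ᵢ) / Σᵢ μ̄ᵢ²` over genes with μ̄ ≥ 1. Two alternatives were
  rejected on statistical grounds: the *median* of per-gene estimates is
  biased low at 2 df (the median of a χ²₂-shaped variance estimate is ~0.69
  of its mean, and the max(0, ·) clamp pushes it further), which makes the
  downstream Wald test anticonservative; the *unweighted mean* of per-gene
  ratios is dominated by low-expression genes whose μ̄² denominator explodes.
  The ratio-of-sums weights genes by μ̄², is consistent under a common α, and
  holds the null Wald rejection rate at its nominal level in the
  calibration test.
* `moderated` (default): gene-wise estimates shrunk toward the pooled value
  with weight `df/(df + prior_df)` (prior_df = 8, so weight 0.2 at 2 + 2)
  and floored at the pooled value. The floor means a gene with visibly
  elevated replicate scatter is never tested with an optimistic variance —
  a deliberately conservative stance for low replication, in the spirit of
  early NB-test practice of taking the maximum of gene-wise and fitted
  dispersions — while the shrinkage keeps the noise of 2-df moments from
  destroying power.

**Wald test.** Per gene, `log2fc = log2(m₁/m₀)` with `m_c` the mean of
normalized counts in condition *c*. The standard error follows from the
plug-in NB variance of each group mean, `var(K/sf) = μ/sf + αμ²`:

```
se² = [ v₀/m₀² + v₁/m₁² ] / ln(2)²,   v_c = (m_c Σ_j 1/sf_j + α m_c² n_c) / n_c²
```

`wald = log2fc/se` is referred to the standard normal, two-sided. A
pseudo-count of 0.5 replaces a *group mean* of zero (not every count), so
fold changes of expressed genes are unbiased while all-zero groups stay
finite; genes with fewer than `min_count = 10` total raw counts are flagged
`low_count` and excluded from testing and from the BH family (method-of-
moments dispersions are unusable there). Calls use the rule
`padj < 0.05` **and** linear fold change > 1.5; both cutoffs are arguments.
The fold change used for the 1.5× rule is the raw estimate — no shrinkage is
applied anywhere, and that choice is deliberate: with a shrunken estimator
the fold-change filter would depend on the shrinkage strength, which this
package does not model.

**Translation efficiency.** TE is Ribo-seq signal normalized by RNA-seq
signal, so a TE change is the interaction contrast
`ΔTE = log2FC(Ribo) − log2FC(RNA)`. Each assay gets its own size factors and
dispersions; the two fold changes come from disjoint libraries, so they are
treated as independent and `se = sqrt(se²_Ribo + se²_RNA)`. Wald, BH and the
call rule are as above. This difference-of-contrasts instantiation is this
package's own: it is the simplest estimator consistent with "Ribo normalized
by RNA", and its properties (transcriptional effects cancel exactly;
genome-wide calibration) are what the tests verify.

## Motif scanning conventions

The consensus expands to exactly six strings ({A,G} × {U,UU,UUU} × AGU).
Conventions, each chosen to be deterministic and oracle-checkable:

* Overlapping occurrences count at their distinct offsets; at a single
  offset at most one n can match (the base after the U-run differs), so
  "longest n wins" is vacuous but documented for safety.
* Sense strand only: the motif is a property of the mRNA.
* A hit spanning a feature boundary is annotated by its start position.
* *Duplicate* means ≥ 2 occurrences anywhere in the TU — the protein's two
  RRMs each engage one site, and no maximal spacing between sites is
  asserted by the biology; a `max_spacing` cap is exposed for sensitivity
  analyses and is off (`Inf`) by default. The cap restricts only the
  duplicate flag (and hence direct-target calls), never the raw count.
* Coordinates are 0-based half-open internally; GFF3 I/O converts to/from
  1-based inclusive; FASTA is written in DNA spelling (U→T) at 80 columns.

Direct-target classification is the conjunction rule: a gene is a
`direct-candidate` only when it is TE-significant *and* its TU meets the
motif criterion (duplicate by default); TE-significant without motif support
is `indirect` — the signature of burden rather than binding.

## Enrichment

One-sided Fisher exact test (hypergeometric upper tail): the direction of
interest is over-representation, and reporting enriched terms only is the
convention in this setting. The odds ratio is the sample estimate with a
Haldane 0.5 added to all cells only when one is zero, and only for display —
p-values are never continuity-corrected. Terms smaller than
`min_term_size = 3` are skipped to avoid degenerate rows. The test is exact
and discrete, so under a random gene list the rejection rate at 0.05 is
slightly *below* 0.05; the null-calibration test asserts precisely that.

## Reporter model

Expression is `(F_raw − F_bg)/(A_raw − A_bg) − F_auto` with backgrounds from
medium-only wells and autofluorescence from non-transformed cells.
Post-subtraction values may be slightly negative under noise; they are kept
(with a flag) rather than clamped so that replicate averages stay unbiased.
Repression is computed from replicate-*mean* expressions (ratio of means),
matching mean ± SD triplicate reporting; a mean-of-per-replicate-ratios
alternative is exposed (`per_replicate = TRUE`) because the two estimators
differ under noise and the field's reporting does not pin one down — at zero
noise they agree exactly, which is tested.

The two-motif prediction assumes independent site occupancy: if expression
passes each occupied site independently, `E = E₀(1 − θ_RBS)(1 − θ_AUG)`, so
fold changes multiply: `fold_two = fold_RBS × fold_AUG`. On that occupancy
model the identity is exact (tested on a 20 × 20 occupancy grid to machine
precision); on real data deviations from the product quantify cooperativity
or interference, which `compare_prediction()` reports as a log2 error.

## Serial-passage accounting

A daily bottleneck of fraction *b* with regrowth to the pre-dilution density
is `log2(1/b)` doublings per day — 6.64 for 1:100 — with no lag- or
death-phase correction, the implicit assumption behind that figure.
Loss of function is called from daily dynamic-range trajectories by a
threshold-persistence rule: first day below `threshold` staying below for
`persistence` consecutive days. The biology fixes no numeric criterion, so
both are mandatory, documented defaults (threshold 2, persistence 2 days):
threshold 2 is the natural "no useful regulation left" boundary
(a functional circuit shows ~10-fold range), and two days of persistence
reject single-day measurement dips. Days are 1-based in all reports.

## The synthetic-data generator

The generator produces every input with recorded ground truth:

* **Transcriptomes**: polycistronic TUs (1–3 genes; 5'UTR 20–60 nt, CDS
  30–100 codons, terminal 3'UTR) whose background sequence is
  rejection-sampled to contain *no* accidental consensus occurrence (any
  accidental hit has a uridine rewritten to C, which can never create a new
  hit since no pattern contains C); planned motifs are then spliced in at
  recorded non-overlapping offsets and the TU re-scanned to confirm the
  planted set is exactly what any scanner will find. This gives scanner
  tests exact expected counts at the cost of a small composition bias
  (scrubbed background is slightly C-enriched and depleted of one specific
  pentamer family), which is irrelevant to the scanning logic under test.
* **Counts**: NB draws from the model above, with per-sample size factors
  uniform on [0.8, 1.2], log-normal baselines (meanlog log 300, sdlog 1 —
  a realistic bulk dynamic range), a per-gene log-normal translation factor
  τ (sdlog 0.3) relating Ribo to RNA means, dispersion 0.05, and two
  replicates per condition, mirroring the duplicate library design.
* **Plates**: `F_raw = (signal + autofluorescence)·A + F_bg + noise`,
  `A_raw = A + A_bg`, plus blank and non-transformed wells, so the reporter
  reduction inverts the acquisition exactly at zero noise.
* **Evolution lines**: per line and element the mutation day is geometric;
  after a ≥ 1 day takeover lag (the sweep under a 1:100 bottleneck) the
  dynamic range steps from functional to lost.

One global seed expands into per-stage child seeds through a fixed integer
recurrence (`derive_seed()`), so stages are independently regenerable and
whole runs byte-reproducible.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: read-level artifacts (alignment, rRNA
contamination, footprint-length effects), gene-specific dispersion trends,
correlated library composition biases, plate edge effects, and partial
population takeovers that produce intermediate dynamic ranges. Conclusions
about the *statistical machinery* transfer; conclusions about any particular
real library do not.

## Problem sizes and numerical choices

The test-suite and acceptance scenarios use 2000 genes at 2 + 2 replicates
for genome-scale checks and 100–500 genes elsewhere — large enough that
binomial error on a rejection rate is ~±0.01 and small enough to keep the
whole suite fast at a single core. Planted "strong" TE effects are
|log2| = 3: a power analysis at these conditions shows a genome-wide BH call
needs a Wald statistic ≳ 4.3, which an 8-fold shift clears comfortably while
a 4-fold shift sits at the boundary. Note that even then, exact recovery of
a planted 2-gene set is a stochastic event: BH at FDR 0.05 across 2000 genes
admits one borderline extra call in a minority of datasets — that is the
designed behavior of FDR control, not a defect, and the same caveat applies
to any genome-wide screen with two replicates.

Ties in BH are broken by a stable sort on (p, gene id); the adjustment
itself is order-invariant, so this matters only for reproducible row order.
Degenerate inputs are reported, not silently fixed: no gene expressed in
every sample fails size-factor estimation; an all-zero gene is `NA`
dispersion and `low_count`; absorbance at or below background is an error;
`E_on = 0` yields an infinite fold with a warning.
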