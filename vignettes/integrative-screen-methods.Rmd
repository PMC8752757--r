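---
title: "Methods: the integrative HGSOC tumor-suppressor screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the integrative HGSOC tumor-suppressor screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoscreen)
```

This vignette documents the models, parameter choices and numerical
conventions behind each stage of the pipeline, what the synthetic-data
generators do and do not emulate, and the design decisions taken where the
procedure left room for interpretation.

## The consensus screen

Each expression cohort is a genes × samples matrix already on the log2
scale, with a two-group design (control epithelium vs tumor). Per gene we
compute an unpaired two-sided t test — the pooled-variance Student form by
default, because that is the test quoted for the two-group comparisons;
the Welch form is available as `method = "welch"` for heteroscedastic
inputs. The significance rank orders by ascending p, breaking ties by
descending |log2 fold change| and then by symbol, so rankings are total and
reproducible. Duplicate gene symbols (multiple microarray probes per gene)
collapse to the most significant probe *before* ranking, mirroring how
probe-level series are reduced to gene-level lists.

The consensus step intersects the top-*k* gene sets of the per-dataset
rankings and keeps only genes whose fold-change direction agrees everywhere.
We interpret "top *k*" as top *k* by significance irrespective of direction,
with direction enforced at intersection time; an alternative reading (top
*k* per direction) exists, but the direction-agnostic rule already yields a
small, sign-consistent candidate set on cohort-sized simulations, which is
the observed behavior of the screen. Candidates are ordered by their worst
per-dataset rank, so a gene must rank well in *every* cohort to lead the
list. The external-cohort validation step is implemented as a pure sign
cross-check against a user-supplied gene → sign map, deliberately offline.

The gene-set overlay reports two complementary p-values: a hypergeometric
upper tail for set membership among genes significant (BH q < 0.05) in the
stated direction — sharp when there are many significant genes — and a
one-sided rank-sum test on the set's t statistics against the rest of the
table, which remains informative (and uniform under the null) even when no
gene passes the significance cutoff. Null calibration in the test suite uses
the rank-sum component for exactly that reason: on a null table the
significant-gene set is empty and the hypergeometric p degenerates to 1.

## The survival cut-point scan

`quantile_split(cohort, high_fraction)` labels the
round-half-up(`high_fraction` · n) samples with the largest expression
"high". Round-half-up is a deliberate choice: it reproduces the published
297 low / 128 high division of a 425-patient cohort at the 70/30 ratio, and
at `high_fraction = 0.7` gives 298 high (297.5 rounds up). A 10⁻⁹ guard is
added before flooring because products such as 0.7 × 425 evaluate a hair
below 297.5 in binary floating point. Expression ties are broken by a stable
sort on (expression, sample id), making the split invariant to row order.

`scan_cutpoints` follows the published convention of naming each candidate
cut by its *low*-group share: the ratio *f* divides the fraction *f* of
samples into low expression and 1 − *f* into high, so the "70% ratio" is the
297/128 split above. The scanned ratios default to 30/50/70%, the selected
ratio minimizes the log-rank p (ties to the smallest ratio), and all
per-ratio results are always returned together with a BH adjustment across
the scanned ratios. This matters because choosing the best of three
correlated tests is anti-conservative: under a zero-effect generator the
selected-split p falls below 0.05 in roughly 10–13% of runs, not 5%. The
package treats that optimism as a property to be measured and reported — the
test suite asserts that the inflation exists — rather than something to be
silently absorbed.

The log-rank statistic uses the tie-aware hypergeometric variance (survival
data are full of tied times); Kaplan–Meier curves come from the standard
product-limit estimator with censoring handled by risk-set reduction.

## The CNA landscape

Discrete copy-number categories are taken as input in the cBioPortal coding
(−2 deep/bi-allelic deletion, −1 deletion, 0 diploid, +1 gain, +2
amplification); the pipeline never re-derives calls from linear ratios,
because published cohorts ship the calls. Expression across categories is
tested by fixed-effects one-way ANOVA; categories with fewer than two
samples are dropped with a message rather than failing, because extreme
categories (+2 especially) are near-empty at many loci. Neighboring loci are
compared by Pearson correlation of relative linear copy number; paralog
families by all pairwise 2×2 Fisher exact tests per event type
(amplification, deep deletion), BH-adjusted across pairs. When neither gene
of a pair carries the event the comparison is vacuous and we record p = 1
instead of erroring on a degenerate margin.

## The motif stage

Phosphosite windows span offsets −5…+5 around the phosphorylated S/T
(11 residues, matching the printed 11-symbol pattern), gap-padded at
sequence termini. Consensus inference is column-wise: one distinct non-gap
residue → fixed position; two or three → bracketed class; four or more →
wildcard `x`. The 2–3 class threshold (`max_class = 3`) reproduces the
printed bracket sizes with four substrate windows. Class residues are
ordered by decreasing frequency; frequency ties break by first occurrence
across the *lexicographically sorted* windows — sorting first keeps the
inference invariant to the order in which windows are supplied, and this
rule reproduces the printed bracket orders (`[AVM]`, `[ILV]`), which a plain
alphabetical tie-break would not.

Two interpretation decisions are worth stating prominently. First, the
notation's `x` ("optional") is read as *exactly one arbitrary residue* — a
standard wildcard — not as a deletable position: the printed motif aligns
S\* at a fixed offset, and the comparison with the fixed-spacing 14-3-3
pattern presumes fixed spacing. Second, the 14-3-3 pattern `R[ST]xSxP`
carries no phospho-star, so co-matching anchors its second serine (the 4th
symbol, the mode-1 14-3-3 phosphosite) on the candidate site, i.e. the
pattern covers offsets −3…+2. Scanning is conservative at termini: any
non-wildcard position falling outside the sequence fails the match. Protein
positions are 1-based throughout.

## The ATAC stage

Peak raw counts are quantile-normalized (all samples forced to the
distribution of across-sample rank means; within-column ties receive the
mean of their rank values) and each peak scored by the mean
log2(normalized + 1) difference, condition minus control. A per-peak test
was deliberately avoided: replicate counts in ATAC designs are small, and
the score only feeds a rank-based enrichment. Note that exact column-wise
distribution equality and idempotence of quantile normalization hold for
tie-free matrices; with tied counts, tie-averaging makes both approximate by
construction.

Motif occurrence uses a log2-odds PWM scanner over JASPAR-format position
frequency matrices: pseudocount 0.5 per cell, uniform background, both
strands, hit threshold at 80% of the maximum attainable score, `N` scoring
as background. All four knobs are exposed; the defaults are the common
choices for occurrence calling when the upstream tool is unspecified.

The module-map integration is a declared simplification: for each motif, a
hypergeometric upper-tail p of motif presence among the top 5% and bottom 5%
of peaks by differential score, BH across motifs within each direction, and
a signed score −log10(q) carrying the sign of the dominant direction. The
original module-level machinery (module definitions, iterative refinement)
is out of scope; what the pipeline needs from it — a signed per-motif
significance ranking — is exactly what this produces. Exact reproduction of
any published motif ranking is therefore not claimed.

## The synthetic generators

Every generator is a pure function of (`generator_spec`, seed) and returns a
machine-readable truth object; the test suite consumes the truth directly.
Defaults encode the study conditions:

* **Expression** (`make_expression_pair`): 2,000 genes, 10 samples per
  group (overridable per dataset to emulate the 10 vs 53 and 10 vs 185
  series), 50 shared true DE genes plus 25 dataset-private decoys, effect
  size 2.0 on the log2 scale, Gaussian noise SD 0.5 — log2-scale Gaussian
  noise matches log2-fitted microarray intensities. Probe effects, batch
  effects and inter-gene correlation are *not* emulated, so passing recovery
  tests demonstrate the screen's logic, not robustness to array artifacts.
* **Survival** (`make_survival_cohort`): n = 400, exponential event times at
  baseline hazard 0.02/month (median ≈ 35 months, a realistic HGSOC overall
  survival scale), hazard ratio 3 above the 70th expression percentile,
  30% independent censoring. The hazard is a *step* in expression, not
  proportional — a step is the structure the cut-point scan is designed to
  detect, which makes recovery of the 70% ratio a sharp test.
* **CNA** (`make_cna_cohort`): loci share a latent Gaussian state along a
  chain with adjacent correlation 0.9 (correlation decays with chain
  distance); linear copy number is lognormal around the latent state
  (2^(0.25·z)); categories are cohort-relative quantile calls matching the
  configured category profile (deletion-dominant by default, 38.4%
  deletion); expression is linear in category plus noise. The near-linear
  latent → linear map was chosen deliberately: a numerical experiment at
  design time showed that forcing fixed log2 category thresholds onto an
  arbitrary category profile requires a strongly nonlinear map that
  attenuates the planted Pearson correlation from 0.9 to ≈ 0.87, destroying
  CI coverage of the recovery test; with the lognormal map the attenuation
  is ≈ 0.001 and coverage is nominal. The fixed thresholds (±0.3, ±1.0 in
  log2) remain documented as the *meaning* of the category labels, not as a
  transformation the generator applies.
* **Proteome** (`make_proteome`): 50 proteins × 1,000 residues, uniform
  amino-acid background, 20 exact motif realizations planted at
  non-overlapping recorded positions, half marked mass-spec-confirmed.
  Real proteomes are not compositionally uniform; background match-rate
  expectations in the tests use the uniform model only.
* **Peaks** (`make_peakset`): 2,000 peaks × 200 bp, motif consensus embedded
  in 5% of peaks, negative-binomial counts (size 10) around a lognormal
  per-peak baseline of mean 50, 3 + 3 samples, condition-group mean of
  motif-bearing peaks multiplied by 0.25 (a 4-fold accessibility loss).

## Problem sizes and repetition counts

Simulation-backed checks use: 200 replicates for the cut-point selection
rate and its null optimism (n = 400 and n = 200 cohorts respectively), 100
replicates for the enrichment-ranking recovery (500 peaks, 4 motifs per
replicate), 200–500 replicates for null false-positive calibrations, and
single seeded runs for recall and correlation recovery at the default sizes.
These sizes give binomial standard errors comfortably inside the asserted
bands while keeping the default test run short.

## Known limitations

* The per-gene tests are plain (unmoderated) t statistics; empirical-Bayes
  variance shrinkage is intentionally out of scope, so very small groups
  rank noisily compared to moderated pipelines.
* The cut-point scan reports, but does not correct beyond BH-across-ratios,
  the selection optimism; any genome-wide use must additionally adjust
  across genes.
* The PWM scanner calls occurrence, not affinity; thresholding at 80% of
  the maximum score is a convention, and motif rankings shift with it.
* The generators model independent genes, peaks and samples; correlated
  structure (LD-like blocks, batch effects, co-regulated modules) is not
  emulated, and conclusions about real-cohort robustness should not be drawn
  from recovery rates alone.
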