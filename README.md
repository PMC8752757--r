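# oncoscreen

An R implementation of the integrative in silico screen used to nominate
candidate tumor suppressors — the kinase MARK3 foremost among them — in
high-grade serous ovarian carcinoma (HGSOC). The package turns the screen's
five computational stages into tested, reusable functions, and ships seeded
synthetic-data generators with known ground truth so that every stage runs,
and can be validated, without downloading any cohort.

## What the pipeline computes

1. **Cross-dataset DEG consensus screen.** For each expression cohort
   (genes × samples, log2 scale, normal vs tumor), per-gene unpaired t
   statistics give a significance ranking; the screen intersects the top-*k*
   (default *k* = 100) gene sets of two independent cohorts and keeps genes
   whose fold-change sign agrees, ordered by worst per-dataset rank. A sign
   cross-check against an external cohort and a hypergeometric + rank-sum
   gene-set overlay (e.g. Hippo signature genes) complete the stage.
2. **Survival cut-point scan.** A cohort (time, event, one gene's
   expression) is cut at the 30/50/70% expression quantiles; each split is
   tested with the tie-aware log-rank test and the most significant ratio is
   selected — with all per-ratio p-values reported, because selecting the
   best split post hoc inflates the false-positive rate (the package
   measures that optimism rather than hiding it). Kaplan–Meier curves and
   numbers-at-risk tables are exported for the chosen split.
3. **CNA landscape.** Discrete copy-number categories (+2 amplification …
   −2 deep deletion) are profiled per locus; expression across categories is
   tested by one-way ANOVA; neighboring loci are compared by Pearson
   correlation of relative linear copy number; paralog families are
   contrasted by pairwise Fisher tests of amplification / deep-deletion
   frequency with BH adjustment.
4. **Kinase-substrate motif analysis.** ±5-residue windows around known
   substrate phosphosites are aligned into a consensus motif (fixed
   positions, bracketed residue classes of up to 3 residues, `x`
   wildcards) — the four engineered substrate windows reproduce
   `LxRxxS*[AVM]Pxx[ILV]`. The motif is scanned over a proteome, and
   candidate sites are annotated with mass-spec confirmation and co-match of
   the 14-3-3 binding pattern `R[ST]xSxP`.
5. **ATAC motif enrichment.** Peak raw counts are quantile-normalized; each
   peak gets a signed differential-accessibility score (mean log2
   difference); a peak × motif occurrence matrix from a log-odds PWM scanner
   (JASPAR-format inputs, both strands) is integrated with the scores by
   top/bottom-tail hypergeometric enrichment with BH adjustment — a
   simplified module-map integration producing a signed per-motif ranking.

A shared statistical kernel (t, ANOVA, Pearson, Fisher exact, log-rank,
Kaplan–Meier, BH FDR, hypergeometric tail, quantile normalization) backs all
stages and is oracle-tested against closed forms and enumerations.

## Worked example

The survival stage, end to end on a simulated 400-patient cohort with a
3-fold hazard step above the 70th expression percentile:

```r
library(oncoscreen)
sc <- make_survival_cohort(generator_spec(20260924))
scan <- scan_cutpoints(sc$cohort)
scan$per_fraction
#>   fraction n_low n_high     chisq            p            q
#> 1      0.3   120    280  6.884063 8.696763e-03 8.696763e-03
#> 2      0.5   200    200 19.321067 1.104806e-05 1.657209e-05
#> 3      0.7   280    120 67.846781 1.767068e-16 5.301204e-16
scan$selected_fraction
#> [1] 0.7
```

The scan recovers the planted cut: the 70% ratio (280 low / 120 high) is by
far the most significant split. Each row is one candidate ratio: `n_low` /
`n_high` are the group sizes, `chisq` and `p` the log-rank test of that
split, `q` the BH adjustment across the three tested ratios. On a 425-sample
cohort the 70% ratio reproduces the published 297 low / 128 high split.

The motif stage in three lines:

```r
windows <- c("LARFGSAPDHI", "LCRGHSVPEKL", "LDRHISMPFMV", "LERIKSAPGNI")
render_motif(infer_consensus(windows))
#> [1] "LxRxxS*[AVM]Pxx[ILV]"
```

The `analysis/` directory holds five numbered drivers
(`01_deg_screen.R` … `05_atac_enrichment.R`), one per stage, each a short
narrative script that simulates its inputs, runs the stage and writes its
tables under `results/`.

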