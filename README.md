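# coderegmiR

Cross-series miRNA microarray meta-analysis with co-deregulation scanning.

## The problem

Different pediatric central nervous system (CNS) tumor entities —
medulloblastoma, astrocytoma, ependymoma, glioblastoma, ATRT and others —
each have their own deregulated miRNAs, but a miRNA that is shifted in the
*same direction in (nearly) every tumor sample regardless of entity* is a
candidate pan-tumor biomarker or therapeutic target. Finding such miRNAs
requires pooling many microarray series that were run on different
platforms, measure partially overlapping miRNA universes, and carry
series-level batch effects.

`coderegmiR` implements that analysis as a tested, reusable R pipeline:

1. **Ingest** — harmonize platform-specific miRNA spellings onto canonical
   symbols (`hsa-miR-376b-3p` → `MIR376B`, arm recorded), stack all series
   into a sparse features × samples *hyper-matrix* whose cell is `NaN`
   wherever a series did not measure a symbol (block-diagonal missingness),
   and apply the cohort age-exclusion rule (default: age > 60 y).
2. **Preprocess** — multiplicative background correction
   (`log2(fg) − log2(bg)`; series without a background channel pass through
   as `log2(fg)`), masking of negative values as `NaN`, normalization by
   quantile / loess / rank-invariant schemes (NaN-aware), global-mean
   rescaling `X_ij = x_ij / x̄_total` (equivalently
   `X_ij = 2^(log2(x_ij / x̄_total))`, which fixes the non-missing mean at
   1), and within-symbol replicate averaging.
3. **Differential expression** — per-symbol two-sample t-tests
   (pooled-variance by default, Welch available) with Benjamini–Hochberg
   FDR, plus the log2 tumor/control-mean ratio matrix
   `E_ij = log2(F_tumor,ij / F̄_controls,j)` ("ratios") alongside the
   normalized intensities ("naturals").
4. **Clustering** — Lloyd k-means (squared Euclidean, k-means++ seeding,
   best of restarts) with the Calinski–Harabasz criterion
   `CH = [B/(k−1)]/[W/(n−k)]` for choosing k, hierarchical sub-clustering,
   sorted centroids, and descriptive (group-mean) clustering over
   diagnosis/grade categories with ordered-pattern detection (ANOVA +
   Bonferroni post hocs).
5. **Co-deregulation scan** — the core statistic: for every differentially
   expressed miRNA, the count *f* of tumor samples with `E` above (up) or
   below (down) zero, the percentage *f%*, and its frequency band
   (100, 90–99, 80–89, 75–80 % of samples), reported per k-means cluster,
   plus chromosome/cytoband expression summaries.
6. **Diagnostics** — ROC/AUC per marker via the Mann–Whitney identity, and
   stratified cross-validated Gaussian naive Bayes classification;
   chi-square / odds-ratio / relative-risk / absolute-risk cohort
   association statistics.

A first-class synthetic-data generator (`generate_multiseries()`) emulates
the multi-series structure — overlapping feature universes, batch effects,
background channels, non-positive intensities, planted globally up-/
down-regulated miRNAs at configurable penetrance, grade-ordered signatures,
over-age decoy samples — so the whole pipeline is testable without any
external download.

## Worked example

```r
library(coderegmiR)

sim <- generate_multiseries(synthetic_config(seed = 1))
run <- run_pipeline(sim$series, sim$metadata)

run$manifest[c("n_symbols", "n_samples", "n_samples_excluded",
               "n_de_selected")]
#> $n_symbols         200
#> $n_samples          60
#> $n_samples_excluded  3
#> $n_de_selected      10

head(run$codereg[, c("symbol", "direction", "f", "f_pct", "band")], 6)
#>    symbol direction  f f_pct  band
#> 1  MIR149      down 40 100.0   100
#> 2  MIR214      down 40 100.0   100
#> 3  MIR574      down 40 100.0   100
#> 4  MIR595      down 40 100.0   100
#> 5  MIR765      down 40 100.0   100
#> 6  MIR372        up 35  87.5 80-89

sapply(run$roc[c("MIR149", "MIR214", "MIR574", "MIR595", "MIR765")],
       function(x) round(x$auc, 3))
#> MIR149 MIR214 MIR574 MIR595 MIR765
#>  0.998  0.999  0.999  1.000  0.999

run$nb
#> naive Bayes 5-fold CV: mean accuracy 1.000
```

Reading: the three >60-year decoy samples were excluded; the five miRNAs
planted down-regulated in every tumor are recovered exactly in the 100 %
frequency band with negative mean expression, each separating tumors from
controls with AUC ≈ 1; the partially penetrant up-regulated markers land in
the 80–89 / 90–99 % bands, as planted.

The package also ships the published co-deregulation frequency table and
cohort count margins of a reference pediatric CNS tumor study
(`cns_codereg_reference()`, `cns_cohort_reference()`), used for
frequency-arithmetic and band-census checks against printed values.

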