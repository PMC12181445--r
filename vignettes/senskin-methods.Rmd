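---
title: "Methods: scoring and enrichment of a signed skin-senescence signature"
author: "SenSkinTools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and enrichment of a signed skin-senescence signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models and procedures, the parameters that matter and their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices made where more than one reasonable reading existed.

# The signed signature

The packaged SenSkin set contains 165 gene symbols: 164 expected
up-regulated in senescent skin cells and one expected down-regulated
(*LMNB1*, whose loss is a classic senescence marker). The symbols live in a
plain-text data file (`inst/extdata/senskin_genes.tsv`, one symbol per line
with an up/down column) whose MD5 checksum is asserted by the test suite:
any edit to the file, however small, fails the build loudly. Gene-symbol
matching everywhere in the package is case-insensitive and
whitespace-trimmed, with no alias or HGNC resolution — the signature is
defined over bare symbols, and resolving aliases would silently couple
results to an external database version.

Because standard GMT has no direction field, signed sets are serialized as
`<NAME>_UP` / `<NAME>_DN` line pairs; a line without either suffix reads as
an unsigned (all-up) set. The writer emits exactly what the reader parses,
and round-trip identity is tested.

# Composite per-cell score

Counts are log-normalized as `ln(1 + c/total × scale)` with `scale = 1e4`
(the dominant single-cell convention; the scale is a parameter), then each
gene is standardized to z-scores. The score of cell *c* is

    score(c) = mean(z of up-genes present) − mean(z of down-genes present)

Decisions worth recording:

* **Missing genes shrink the divisor.** The normalizing constants are the
  numbers of signature genes actually present in the matrix, not the
  nominal 164/1. With a complete matrix the two definitions coincide; under
  missingness dividing by the nominal count would shrink scores toward zero
  for reasons unrelated to biology. The counts used are recorded in the
  result metadata, and a missing down-stratum degrades to a zero second
  term with a warning.
* **Z-scores are computed jointly across all cells**, not within dataset or
  condition. Per-condition standardization would erase exactly the
  condition contrast the score exists to measure.
* **Sample standard deviation** (n−1) is the default denominator; the
  population option changes every score by the same factor and no ordering
  or test decision.
* Zero-variance genes become all-zero z-rows rather than NaN; cells with
  zero totals are dropped with a warning, never imputed.

# Per-cell-type contrasts

Scores are compared between the two conditions within each cell type using
the **unpaired Wilcoxon rank-sum (Mann–Whitney) test**. Violin-plot
comparisons of this kind are sometimes described as "signed-rank" tests,
but cells from two donor cohorts are not paired observations; the
signed-rank test is offered behind `paired = TRUE` for genuinely paired
designs, and the rank-sum test is the default. We rely on
`stats::wilcox.test`'s own switching rule between the exact distribution
(both groups < 50, no ties) and the normal approximation with continuity
correction; the exact small-sample behaviour is pinned by a test that
enumerates all 20 labelings of {1,2,3} vs {4,5,6} (two-sided p = 0.1).

Multiplicity across cell types is Bonferroni by default, matching the
package's differential-expression convention, with BH available. Cell
types with fewer than two cells in either condition are flagged
`insufficient` and excluded from both testing and the adjustment family.
Direction (`up`) means the second condition — aged/UV-exposed in the
simulated designs — has the higher median.

# Pseudobulk correlation clustering

Single-cell counts are summed per sample (per donor) to form pseudobulk
columns. Summation of raw counts is the default aggregation because it
preserves count additivity (tested as an exact conservation law);
mean-of-lognormalized is available. Whether to group by sample, cell type
or both is exposed (`groupby`); the pipeline default is by sample, which
yields bulk-like profiles in which inter-gene correlations reflect shared
regulation across donors.

Before correlating, per-gene **skewness** is measured. The default
estimator is the adjusted Fisher–Pearson `G1 = g1·sqrt(n(n−1))/(n−2)` —
the common default in statistical software — with the uncorrected `g1` and
`b1` variants selectable, since a "skewness > 2" gate can flip genes near
the threshold depending on the estimator. If any gene exceeds the
threshold (default 2), the **whole matrix** is log-transformed (`ln(1+x)`)
in the default `global` mode: that is the plain reading of a rule that
log-transforms expression because some genes are skewed. The alternative
reading — transform only the offending genes — is implemented as
`per_gene`, and the mode is an explicit argument rather than a silent
heuristic. The triggering genes are always reported.

Correlation is Pearson on the (possibly log-transformed) rows by default —
standardization does not change Pearson r — with Spearman selectable.
Zero-variance genes are flagged and assigned correlation 0 off-diagonal.
Clustering is agglomerative with **complete linkage on d = 1 − r**, not
1 − |r|: anticorrelated genes belong in different clusters, preserving the
sign structure a correlation heatmap displays. The tree is cut at k = 5 by
default (k is a user choice; no automatic selection is attempted), and
cluster labels are renumbered by dendrogram position so cluster 1 is the
leftmost block and every cluster is contiguous along the leaf order — an
invariant enforced by the class validity method. Merge heights are
non-decreasing for complete linkage, and the whole agglomeration is checked
against a naive O(n³) pair-scanning oracle on random correlation matrices
in the tests. Ties in merge distance are broken toward the lowest-index
pair; with continuous correlations ties essentially never occur, and for
tied block structures the merge heights and cut partitions are
tie-invariant even where merge order is not.

# Phenotype-permutation GSEA

The engine pins the classic tool's defaults explicitly so results do not
depend on an external implementation:

* **Ranking metric:** signal-to-noise `(μ_A − μ_B)/(σ_A + σ_B)`, with each
  σ floored at `0.2·|μ|` and at 0.2 outright when both are zero. It
  requires at least 3 samples per group. The first factor level is the
  test class; the pipeline ranks with the aged/UV group first so positive
  scores mean enrichment with aging.
* **Enrichment score:** the weighted Kolmogorov–Smirnov running sum with
  hit increments `|metric|^p / NR` (p = 1, `NR` the sum over hits) and
  miss decrements `1/(N − N_hits)`; ES is the signed maximum deviation. A
  numerical near-tie between the positive and negative extremum (|sum| <
  1e−9) resolves to the positive one — a documented deterministic rule,
  verified against a brute-force prefix-scanning oracle on 500 random
  instances and against an independent implementation.
* **Null model:** `n_perm` random relabelings of the samples (default
  1000), i.e. permutation on phenotypes, which preserves the inter-gene
  correlation structure that gene-permutation nulls destroy. Permutation
  group sums are obtained from two matrix products, so the cost per
  permutation is one vectorized metric evaluation and one ranked walk.
* **Normalization and significance:** `NES = ES / mean(|null ES| of the
  matching sign)`; nominal p is the one-sided fraction of matching-sign
  null scores at least as extreme, with an add-one correction so p ≥
  1/(n_perm+1) and never 0; FDR q is the sign-stratified pooled-null ratio
  of the classic procedure, clipped to [0, 1]. When no matching-sign null
  exists, NES and q are reported as NA rather than coerced. FDR < 0.25 is
  the conventional significance threshold for this statistic.
* **"No collapse":** gene identifiers are used as-is; no probe-to-symbol
  mapping is performed.
* The permutation seed is recorded in every result row; a fixed seed gives
  bit-identical output.

# Differential expression and over-representation

`wilcoxonDE` tests each gene between two groups on log-normalized values,
with the marker-detection convention for the natural-log fold change:
`ln(mean(expm1 x_A) + 1) − ln(mean(expm1 x_B) + 1)`, i.e. the log of
shifted means of de-logged values, under which the default cutoff 0.25 is
the familiar one; a plain difference of mean log values is available. A
gene passes at `|lnFC| ≥ 0.25` and Bonferroni-adjusted p < 0.05.

`ora` is the hypergeometric upper tail `P(X ≥ k)` of the query–pathway
overlap against a user-supplied universe, BH-adjusted across pathways with
FDR < 0.05 as the default flag. Pathway collections are supplied by the
user as GMT; no pathway database is bundled, because bundled snapshots go
stale and printed overlap results depend on collection versions.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which everything else is validated. Counts are negative binomial with
gene-specific baseline log-means (`N(ln 0.5, 1.2²)` per gene for
single-cell, `N(ln 100, 1.2²)` for bulk), dispersion 0.4, lognormal
library-size factors (sdlog 0.35), per-cell-type marker boosts drawn
*outside* the signature (so the embedded program is the only systematic
condition difference), and a mild per-donor scaling factor (sdlog 0.1).
The default single-cell design has six skin cell types (fibroblasts,
keratinocytes, T cells, macrophages, pericytes, vascular endothelial
cells) at 120 cells per condition each, two conditions (UV-protected vs
UV-exposed); the default bulk design has 24 samples per group, mirroring a
young-vs-old epidermis cohort.

The senescence program is injected **on the log-mean scale**: affected
cells in the second condition have up-gene means multiplied by
`exp(effectDelta)` and down-gene means by `exp(−downDelta)`, so deltas are
directly comparable to the natural-log fold-change cutoff used downstream.
`affectedFraction` can be set per cell type, which is how the recovery
tests inject the program into exactly two of six cell types.
Ground-truth flags (`truth_affected`) are emitted so recovery metrics
never have to re-derive truth. The per-donor factor multiplies all genes
equally — it is a library-size-like effect that log-normalization removes,
which keeps cells exchangeable under the null and the rank-sum type-I
calibration honest.

What the generator does **not** emulate: batch effects and dataset
integration, doublets, ambient RNA, cell-type abundance shifts between
conditions, and gene–gene correlation beyond cell-type structure. Passing
tests therefore demonstrate statistical correctness of the procedures
under a clean generative model, not robustness to the artefacts of real
integrated atlases.

# Problem sizes and calibration checks

The validation suite exercises the methods at desk scale, chosen to make
Monte-Carlo checks tight without inflating run time:

* Null calibration: 200 replicate bulk datasets (300-gene universe, 24 vs
  24 samples, no injected effect) with 200 permutations each; the GSEA
  nominal-p rejection count at α = 0.05 must fall inside the central 99.9%
  band of Binomial(200, 0.05). The per-cell-type rank-sum contrast is
  calibrated the same way on 200 null single-cell replicates (two cell
  types each).
* Effect recovery: 50 replicates of a 400-gene, six-cell-type design with
  `effectDelta = downDelta = 0.5` injected into fibroblasts and T cells
  only; the contrast must flag exactly those two types (Bonferroni
  α = 0.05) in at least 90% of replicates, and the bulk design at the same
  delta must give positive NES at FDR < 0.25 in the majority of 20
  replicates.
* Oracle equivalence: 500 random ranked-list/set instances (N ≤ 50) for
  the enrichment score, 100 random correlation matrices (n ≤ 8) for the
  clustering, exhaustive enumeration for the small-sample rank-sum test,
  and closed-form hypergeometric tails for ORA.

The acceptance script (`scripts/acceptance.R`) re-runs the default study
designs (2000-gene universe; 24 vs 24 bulk samples with 1000 permutations;
1440 cells across six types) and reports the computed quantities as JSON.

# Known limitations

* The signature is a fixed symbol list; results on platforms that measure
  only part of it (e.g. 145 of 165 genes on some bulk arrays) depend on
  coverage, which `geneCoverage()` reports but cannot repair.
* Applying the package to public aging- or photoaging-skin datasets
  requires preprocessing choices (normalization, filtering, integration)
  that such datasets do not prescribe; the package deliberately validates
  against its own generative model instead of bundling a frozen
  preprocessing of any particular accession.
* The GSEA FDR is the classic sign-stratified pooled-null estimate; with a
  single gene set it can reach exactly 0 when no pooled null score exceeds
  the observed NES, and it is not monotone in NES across sets.
* Scores across cell types share one joint z-scoring, so between-cell-type
  comparisons of absolute score levels partly reflect cell-type abundance
  in the matrix at hand.
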