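---
title: "Module expression scores and chromatin-modifier signatures: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module expression scores and chromatin-modifier signatures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modscore)
```

## The problem

Histone-modifying enzymes — demethylases (HDMs) such as KDM5A and
methyltransferases (HMTs) such as EZH2 — regulate whole sets of target
genes at once. If an enzyme's activity varies between tissues or cancer
types, its *target module* (the ChIP-defined set of genes it binds, or the
genes carrying the histone mark it writes or erases) should move up or down
*coordinately*, and that movement should track the enzyme's own expression.
`modscore` implements the analysis chain that makes this idea quantitative:

1. collapse a probe-level expression matrix to genes and standardize each
   gene across samples;
2. score every (module, sample) pair with an enrichment z-score against a
   null of random same-size gene sets;
3. correlate enzyme expression with module score profiles across samples
   (Pearson);
4. cluster samples by Manhattan distance on normalized expression;
5. quantify RT-qPCR panels by the 2^-ddCt method with well-level QC.

Every stage is validated on synthetic data with planted structure, so the
package ships its own ground truth.

## The module enrichment z-score

For one sample, let `x_g` be the gene-normalized expression values (each
gene centred to mean 0 and scaled to unit s.d. across samples, so values
are comparable between genes). For a module `M` of effective size `m` (its
genes present in the matrix), the observed statistic is the median of
`x_g, g in M`. The null is the distribution of medians of random gene sets
of size `m` drawn **without replacement** from the same sample's values;
with Monte-Carlo draws `M_1, ..., M_D`,

```
z = (median(M) - mean(median(M_d))) / sd_pop(median(M_d))
```

Calls use the two-sided normal thresholds: `z > 1.96` preferential
expression ("over"), `z < -1.96` underexpression ("under"), otherwise "ns".

Numerical conventions, fixed for reproducibility:

* **Median of an even-size set** = mean of the two central order
  statistics (R's default).
* **Null moments** use the *population* s.d. of the sampled medians: the z
  standardizes against the sampled null itself, it is not an inference
  about the null's parameters. A switch is not exposed; the exhaustive
  oracle uses the same convention so the two routes are comparable.
* **Draw count** `n_draws = 10000` by default. The Monte-Carlo error of
  `z` at that depth is well under the 0.1 agreement demanded of it against
  the exhaustive null (see below), and far from the 1.96 decision
  boundary for any realistic module size.
* **Sampling without replacement**: a random module is a set of distinct
  genes, matching how the real modules are defined.
* **Degenerate nulls** (`sd = 0`, e.g. the module is the whole universe,
  or a constant sample): `z = 0` when the observed median equals the null
  mean, otherwise `NA` with call "ns" and a flag.
* **Absent module genes** are dropped with a warning and the effective
  size recorded — never imputed.
* **Determinism**: every (module, sample) pair derives its RNG seed from
  the base seed and the module/sample *names*, so results are independent
  of iteration order and stable under list reordering.
* **Multiple testing**: the raw 1.96 threshold is applied per cell by
  default, which is the convention this analysis style uses; an optional
  Benjamini–Hochberg adjustment across samples (`bh_adjust = TRUE`) is
  available but off by default.

The Monte-Carlo path is implemented in C++ (partial Fisher–Yates per draw,
using R's RNG) because a calibration experiment needs millions of draws.
The independent check is `exact_null()`, a plain-R enumeration of all
`C(n, m)` gene sets (capped at 200,000 combinations), kept deliberately
separate from the sampling code path.

## Correlation signatures

`module_enzyme_correlation()` computes Pearson correlations across samples
between each enzyme's expression row and each module's z-score row, and
among module rows. Module profiles are summarized by their z-rows by
default because the enrichment heatmap is what the signature refers to; a
`use_median_expression` option summarizes a module by its per-sample median
normalized expression instead, and both are exported by the workflow so
they can be compared. Missing values are handled by pairwise-complete
deletion with `n_used` reported; correlations with fewer than 3 complete
pairs or a constant vector are returned as missing with a reason, and no
p-values are attached by default.

## Sample clustering

`cluster_samples()` clusters sample columns agglomeratively under the
Manhattan distance (sum of absolute coordinate differences over
pairwise-complete entries, unscaled). The distance is the method's defining
choice; the linkage is not dictated by it, so the default is **average**
linkage with complete and single available, and the choice is recorded in
the result and the run manifest. Flat clusters are extracted by a requested
`k` (three, in the canonical use) rather than a height threshold.
Determinism: columns are sorted by sample id before clustering, which fixes
the merge order of tied distances, so the output is exactly invariant to
input column order.

## qPCR relative quantification

Well QC follows two literal rules: wells with irregular melt peaks are
*removed* (non-specific amplification); wells with no product or Ct
strictly greater than 35 are *assigned* Ct 40. Quantification then computes
`dCt(s, g) = Ct(s, g) - Ct(s, ref)` within each sample,
`ddCt(s, g) = dCt(s, g) - mean_s' dCt(s', g)` (each gene centred on its
mean dCt across the samples on the array), and `fold = 2^-ddCt`. Folds are
therefore relative to the array-wide mean for the gene — arbitrary units
with 1 meaning "average for this gene" — and per-gene fold changes have
geometric mean 1 whenever no wells were filtered.

Decisions where practice is ambiguous:

* **Assigned-40 wells are included** in the per-gene centering mean (the
  rule assigns a value rather than discarding the well, implying
  inclusion); `exclude_assigned = TRUE` excludes them for sensitivity
  analysis.
* **A failed reference well does not normalize**: if the reference gene in
  a sample was removed, never measured, or itself assigned 40, that
  sample's results are flagged `missing_reference` instead of dividing by
  a fabricated Ct of 40 (which would produce folds off by factors of
  ~2^20).
* **Technical replicates** are averaged on the Ct scale.
* Instrument-level baseline thresholds are taken as given; `plate_id` is
  carried so plate effects can be inspected.
* The shift identity "adding c cycles to one gene well multiplies its fold
  by 2^-c" holds exactly only with a fixed centering baseline; with the
  mean-dCt centering the exact factor is `2^(-c (n-1)/n)` for n samples,
  which the tests assert. A shift common to *all* wells of a sample
  cancels exactly.
* Display clipping for heatmap export: folds clipped to [0, 10] with 1 as
  the neutral midpoint, exported alongside the raw values.

## The synthetic-data generator

`simulate_expression()` draws a one-dimensional latent "enzyme activity"
factor `a_s` per sample (group mean + Gaussian spread) and builds

```
value(g, s) = baseline_g + effect_g * a_s + N(0, noise_sd)
```

with `effect_g = beta_m` for genes of module `m`, the signed loading for
enzyme genes, and 0 otherwise; genes are optionally expanded to several
probes by adding probe-level noise (default s.d. 0.1 on the log2 scale).
One latent factor is the default because a single activity axis suffices to
produce the phenomenon of interest — an enzyme whose target module follows
it and an opposing module that anti-correlates; independent factors can be
emulated by composing scenarios. The RNG stream is partitioned by purpose
(membership, baseline, latent, gene noise, probe noise), so changing one
rate leaves the others' draws untouched, and a scenario plus seed
reproduces bit-identical output.

Default study conditions: 2000 genes, 60 samples in three activity groups
(latent means +2/0/-2, within-group s.d. 1), two modules of 100 genes with
beta +1 and -1, enzyme loadings +1 and -1, residual noise s.d. 0.5,
baseline log2 expression N(7, 1.5^2) — values typical of log2 microarray
intensities. For cluster-recovery experiments the groups are placed at
latent means -3/0/+3 with within-group s.d. 0.5: distinct tissue types
separated by six within-group s.d., so the planted partition is actually
recoverable; under those conditions recovery is usually perfect
(ARI = 1), with an occasional boundary sample chaining between clusters.

The qPCR generator constructs Ct values whose ddCt pipeline output equals
the planted fold changes exactly in the noise-free case. Because ddCt is
centred per gene, only fold vectors with per-gene geometric mean 1 are
identifiable; requested folds are renormalized to geometric mean 1 and the
renormalized matrix is recorded as the truth. A per-sample global Ct shift
(default s.d. 0.5 cycles) emulates loading differences and cancels in dCt.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: array hybridization physics and saturation,
batch and platform effects, correlated noise between genes beyond the
single latent factor, overlapping or hierarchical modules, real tissue
ontologies, and qPCR efficiency differences between primers. Results on
real data depend on those; the tests establish correctness of the
computation, not robustness to every violation of the model.

## Problem sizes used in validation

The test suite and the acceptance script keep simulations small enough to
be routine on a laptop: oracle agreement on universes of 8–12 genes with
50,000 draws; null calibration on a 200 x 50 matrix with 40 modules of
size 20 (2,000 module x sample evaluations at 2,000 draws each); signature
recovery on the default 2000 x 60 scenario at 1,000 draws; cluster
recovery on 500 x 90. These sizes give Monte-Carlo standard errors
comfortably below every tolerance asserted.

## Known limitations

* The enrichment null conditions on the sample's observed values; it does
  not model inter-gene correlation, so z-scores of overlapping or
  co-regulated modules are not independent across modules or samples.
* Modules are treated as flat sets; weights or directions within a module
  are not supported.
* Probe filtering adjudicates only genes with three or more probes; a
  two-probe gene with discordant probes passes through (no evidence which
  probe is faulty) and should be caught by upstream array QC.
* The qPCR module assumes a single reference gene; multi-reference
  normalization is out of scope.
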