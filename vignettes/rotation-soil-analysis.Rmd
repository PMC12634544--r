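---
title: "Methods: soil enzyme stoichiometry, community structure and path modelling for rotation experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil enzyme stoichiometry, community structure and path modelling for rotation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotastoich)
```

`rotastoich` implements the computational chain of a mushroom-crop rotation
remediation study: four ordered treatment stages (B1 untreated control, B2
spent-substrate amendment, B3 first crop, B4 second no-till crop), three
replicate plots per stage, with soil physicochemical variables, five
extracellular enzyme activities, and taxa-by-sample count matrices for the
bacterial and fungal communities. This vignette explains each method, its
assumptions, the tunable parameters, and the design decisions taken where
the design was genuinely open.

## Synthetic data: the study conditions, generated

All downstream stages are exercised on synthetic data whose generating
parameters *are* the study conditions:

- **Soil/enzyme tables.** Each variable is drawn per treatment from a
  normal with the bundled group mean and SD (`soil_param_table()`),
  truncated at zero **by resampling**, not clipping — clipping would put a
  point mass at zero and distort the ANOVA assumptions. Defaults: 4
  treatments × 3 replicate plots, matching a randomized block design with
  three replicates. The plot is treated as the experimental unit;
  within-plot subsample pooling is not modelled, because only plot-level
  means and SDs are specified. Variables are drawn independently (only
  per-variable moments are given); a correlation matrix can be injected via
  a Gaussian copula (`variable_correlation`) to exercise the correlation
  machinery.
- **Count matrices.** Log-scale basis abundances are multivariate normal
  (so the basis is log-normal with known mean vector and covariance),
  treatment fold-changes multiply the basis of selected taxa, abundances
  are closed to proportions, and counts are multinomial at a fixed read
  depth (default 60,000 reads per sample, the usual target depth of
  paired-end amplicon runs). This is exactly the generative model under
  which SparCC's sparsity assumption is meaningful, which makes network
  recovery a fair test: the generator returns the true basis correlation
  matrix as the oracle. Columns always sum to the configured depth.
- **Latent datasets.** Exogenous latent scores are standard normal;
  endogenous scores are the true path combination plus structural noise;
  indicators are `loading × latent` plus measurement noise of variance
  `1 − loading²`. When `noise_sd` is left `NULL` the structural noise is
  chosen so every latent has unit theoretical variance, making the
  configured paths *standardized* coefficients directly comparable to the
  fitted ones.

One global seed expands into named substreams
(`substream_seed(seed, name)`, a documented Horner hash kept below 2³¹),
so adding a generator never perturbs another generator's stream, and every
pipeline artifact is bit-reproducible from the config seed.

What the generators do **not** emulate: sequencing error, chimeras,
taxonomy, rarefaction artifacts, spatial autocorrelation between plots,
and within-plot subsampling. Passing tests therefore demonstrate
correctness of the estimators under their own model assumptions, not
robustness to every artifact of real amplicon data.

## Treatment statistics

Percent change uses the convention `100 × (treatment − control)/control`
and is displayed to one decimal. One-way ANOVA is the classical
between/within decomposition; the rotation's block design is analysed as
one-way (treatment only). Perfect separation (zero pooled within-group
variance, distinct means) is reported as `F = Inf`, `p = 0` rather than an
error; zero *total* variance is an error because the statistic is
undefined.

Letters come from **protected** LSD: pairwise t tests on the pooled MSE
with the ANOVA residual degrees of freedom, run only when the omnibus test
is significant at `alpha` (default 0.05) — otherwise every group shares
"a". The compact letter display uses the insert-and-absorb algorithm in
descending-mean order, so two groups share a letter **iff** their
comparison is non-significant (the test suite re-derives this from the
pairwise p-value matrix by brute force).

Correlation matrices are Pearson with two-sided t-test p-values and the
conventional raw-threshold stars (* 0.05, ** 0.01); p-values are
deliberately not multiplicity-corrected, matching standard reporting of
soil correlation heatmaps. Constant variables yield flagged `NA`s, never a
silent zero.

## Enzyme stoichiometry and vector analysis

Ratios are plain quotients of activities (μmol product g⁻¹ soil d⁻¹):
`BG:(NAG+LAP)` contrasts C- vs N-acquisition investment, `NAG:LAP` fungal
vs bacterial N cycling (> 1 = fungal), `BG:ALP` C vs P strategy, `BG:PPO`
labile vs recalcitrant C decomposition.

The default (`mode = "literal"`) vector analysis works on raw activities:
`L = sqrt([ln BG]² + [ln(NAG+LAP)]²)` and
`A = arctan(ln(NAG+LAP)/ln BG)` in degrees, nitrogen limitation below
45°, phosphorus above, `"balanced"` at exactly 45°. Two numerical
conventions are fixed: `ln BG = 0` with `ln(NAG+LAP) > 0` maps to 90° (the
arctangent limit), and activities at or below 1 (non-positive logarithm)
are **flagged with a warning** rather than clipped, because the angle then
loses its geometric interpretation; classification refuses flagged values.

A second variant (`mode = "relative"`) computes the common
relative-proportion form, `x = BG/(BG+ALP)`, `y = BG/(BG+NAG+LAP)`,
`L = sqrt(x² + y²)`, `A = atan2(x, y)` in degrees. It is provided for
sensitivity analysis because the two conventions circulate in the
literature and give different absolute angles for the same activities.
Note also that angles computed from *group-mean* activities differ from
the mean of *per-sample* angles (the transformation is nonlinear), so
published angle ranges cannot generally be reproduced from group means
alone; the package computes both levels transparently and the two should
not be compared across conventions.

## Diversity, ordination and PERMANOVA

- **Chao1** uses the bias-corrected form
  `S_obs + F1(F1−1)/(2(F2+1))`, defined even without doubletons — the
  right choice for sparse synthetic samples.
- **Simpson** defaults to Gini–Simpson `1 − Σp²` (in `[0,1)`), with the
  classical dominance `D` behind a flag; "Simpson's index" is ambiguous in
  the literature, so the choice is explicit in the output.
- **Bray–Curtis** is computed on raw counts by default (samples generated
  at equal depth need no normalisation); `relative = TRUE` closes samples
  to proportions first.
- **PCoA** Gower-centres the squared distances and eigendecomposes; when
  the most negative eigenvalue's magnitude exceeds 1e-8 (the typical
  non-Euclidean Bray–Curtis case) the Cailliez correction is applied and
  tagged in the result. Explained proportions are relative to the sum of
  positive eigenvalues.
- **PERMANOVA** uses the distance-based pseudo-F with free permutation of
  labels (no strata — the design gives no exchangeability restriction) and
  `p = (1 + #{F_perm ≥ F_obs})/(B + 1)`, so `p ≥ 1/(B+1)`; B defaults
  to 999.

## SparCC networks

The correlation between unobserved basis abundances is estimated from
log-ratio variances `T_ij = var(log x_i/x_j)`: under the sparsity
assumption the basis variances solve the linear system
`[(d−2)I + J] ω² = t`, and
`ρ_ij = (ω_i² + ω_j² − T_ij)/(2 ω_i ω_j)`, clipped to `[−1, 1]`. Pairs
whose |ρ| exceeds the exclusion threshold (default 0.8, at most
`⌊d/3⌋` pairs) are iteratively removed from the system, since strong
pairs violate the sparsity assumption. At least 4 taxa are required or the
basis system is underdetermined.

Zeros are handled by a pseudocount of 1 by default (deterministic —
convenient for reproducible pipelines); Dirichlet resampling of fractions
(`α = count + 1`, 20 inner iterations, element-wise median) is available
by flag and is itself seeded.

Significance: each taxon's counts are permuted independently across
samples (destroying between-taxon dependence, preserving marginals) and ρ
is re-estimated. The default p-value is per-pair,
`(1 + #{|ρ_perm| ≥ |ρ_obs|})/(B + 1)`. A pooled option compares each
observed |ρ| against the null values of *all* pairs; the pipeline uses it
because the per-pair floor of `1/(B+1)`, multiplied by the
Benjamini–Hochberg factor over thousands of pairs, can never reach the
`q < 0.01` retention rule at a feasible B. Even pooled, the smallest
attainable q is about `1/B`, so at least ~200 permutations are needed
before `q < 0.01` is reachable at all.

Edges are retained iff `|ρ| > 0.6` **and** `q < 0.01` (both thresholds
configurable; retention is provably monotone in each). Isolated taxa are
excluded from the node set by default, matching how co-occurrence networks
are usually reported; `keep_isolates = TRUE` reverses this. Counts can be
aggregated to a coarser lineage level (e.g. top-10 phyla) before inference
with `aggregate_taxa()`. Topology metrics — average degree `2E/N`, global
transitivity, density, and greedy-modularity Q — come from igraph; a
brute-force triple-counting and exhaustive-partition oracle verifies them
on small graphs in the tests.

A sobering property worth stating plainly: with only 12 samples the
permutation null of SparCC is extremely wide (even |ρ| ≈ 0.95 is common
under the null), so **no edge can honestly pass `q < 0.01` at that sample
size** — the bundled demonstration pipeline therefore reports an empty
network, and that is the correct answer, not a defect. The estimator's
power is demonstrated at 200 samples, where a planted basis correlation of
0.9 is recovered as the top-ranked pair and survives thresholding.

## PLS path modelling

The from-scratch PLS-PM estimator standardizes all indicators, starts with
equal outer weights and iterates: latent score = standardized weighted sum
of its block; inner proxy per scheme (centroid = sign of correlation,
factorial = correlation, path = regression weights on predecessors plus
correlations with successors); mode-A weight update = correlation of each
indicator with its block's proxy. Convergence is the maximum absolute
outer-weight change `< 1e-6` (on the unit-variance normalisation, which
fixes the comparison scale), capped at 300 iterations — non-convergence is
an error carrying the last delta, never a silent result. Defaults: path
scheme (the natural choice when a directed inner model is specified; all
three schemes are implemented and agree within 0.05 on well-conditioned
data), reflective mode A throughout.

After convergence, path coefficients are OLS regressions of each
endogenous score on its predecessors (standardized, as the scores are
unit-variance), loadings are indicator–latent correlations, `AVE` is the
mean squared loading per block, and
`GoF = sqrt(mean communality × mean R²)` with the conventional reading
that GoF > 0.6 is excellent for soil–microbe systems. The global sign
indeterminacy of every latent is fixed by requiring its largest-|loading|
indicator to load positively — without this rule bootstrap replicates
could flip sign and wreck the intervals. Bootstrap validation resamples
rows with replacement (default 1,000 resamples), reports percentile 95%
intervals and a normal-approximation p; more than 10% failed refits is an
error with diagnostics, not a quiet average.

The bundled six-latent model (`model_sr_os2.yaml`) encodes the rotation
stage as a single ordinal indicator 1–4 — the stages form a temporal
sequence, so an ordinal encoding preserves their order where one-hot
dummies would discard it — and wires the two remediation pathways:
biological (rotation → soil properties → microbial community → enzyme
ratios) and physicochemical (rotation → micronutrients → enzyme activity →
enzyme ratios). Further inner edges are configurable in the YAML. With 12
replicate-level rows and six latents, fitted coefficients are descriptive,
not confirmatory; the estimator's accuracy is established on the synthetic
latent datasets (a true path of 0.8 with loadings 0.9 at n = 500 is
recovered within ±0.1 — the small attenuation is the well-known PLS-PM
measurement-error bias, which shrinks as block reliability grows).

## Pipeline and problem sizes

`run_pipeline()` chains all stages from one YAML config; every stage's
randomness derives from the config seed via named substreams, and the run
report carries md5 checksums of every artifact, so two runs of the same
config are verifiably identical. A stage failure aborts with the stage
named, leaving earlier artifacts intact; tables are schema-validated
before any computation.

The test-suite problem sizes are the package's own choices: type-I error
rates are estimated from 500–1,000 null replicates at the study's 4 × 3
layout; SparCC recovery uses 40 taxa × 200 samples; PLS-PM recovery uses
n = 500 with 200-resample bootstraps; bootstrap coverage of a zero path is
checked over 200 replications. The demonstration pipeline keeps the
study-sized 12 samples with 120/80 taxa at 3,000 reads per sample.

## Known limitations

- SparCC assumes most taxon pairs are uncorrelated; dense true networks
  bias the basis-variance solution (mitigated, not removed, by the
  exclusion loop).
- Permutation q-values inherit the `~1/B` resolution floor discussed
  above; at replicate-level sample sizes the network stage is honest but
  powerless.
- PLS-PM mode-A path estimates are attenuated by finite block reliability;
  with single-indicator blocks the method reduces exactly to OLS path
  analysis on standardized observables (verified to 1e-8).
- The enzyme vector analysis requires `BG > 1` and `NAG + LAP > 1` in
  literal mode; activities near the unit boundary make angles unstable,
  and flagged samples should be inspected rather than imputed.
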