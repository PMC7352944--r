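---
title: "Methods: biomarker panel discovery from bile omics with synthetic-data augmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarker panel discovery from bile omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilepanel)
```

## The problem

Distinguishing benign from malignant biliary strictures — cholangiocarcinoma
(CCA) or pancreatic ductal adenocarcinoma (PDAC) versus benign cholangiopathy
— is a persistent clinical challenge. Bile collected during ERCP carries
molecular signatures of the underlying disease, and both its lipidome
(~160 MS features on ~130 patients) and its proteome (~2000 proteins on 5
patients per group) have been profiled for candidate biomarkers. Both
regimes are small-n / high-p: classical multivariate methods overfit, and
machine-learning classifiers starve.

`bilepanel` implements a complete discovery pipeline for this setting:

1. **Preprocessing** — kNN imputation, optional log transformation, and a
   ^1^H-NMR processing chain (reference alignment, rectangular bucketing
   with exclusion regions, total-area and probabilistic quotient
   normalization).
2. **Permutation statistics** — exhaustive or Monte-Carlo permutation tests
   replacing parametric inference, group summaries with aggregate ratios,
   and per-feature differential tables with BH q-values.
3. **Synthetic-data augmentation** — per-group means, SDs and correlations
   estimated from the real cohort seed a multivariate-normal generator that
   produces arbitrarily large synthetic training cohorts.
4. **Feature reduction** — three routes: DAPC variable contributions,
   random-forest permutation importance, and per-feature AUC; each yields
   nested candidate panels of 3–10 features.
5. **Classifier selection** — neural networks (NN), Bayesian-regularized
   logistic regression (BGLM), an information-gain decision tree (the C5.0
   family), and a random-forest reference are trained on the synthetic
   cohort and validated on the real table; the best panel × algorithm combo
   wins by validation AUC.
6. **Robustness** — five bespoke permutation tests probe the winner: label
   permutation (Test 1), per-variable corruption (Test 2), all-variable
   corruption (Test 3), single-variable-amid-noise (Test 4), and a full
   pipeline-refit overfitting check under shuffled labels (Test 5).

A synthetic cohort generator with planted ground truth makes every stage
testable end to end without access to patient data.

## The synthetic cohort generator (study conditions)

`cohort_spec()` defaults encode the cohort this package targets: three
groups of 36 benign / 36 CCA / 57 PDAC samples and 162 continuous features,
the lipidomics-like regime. The proteomics-like regime is 5 vs 5 samples
with ~2000 integer features.

The abundance model is log-normal: a latent Gaussian with location
`base_mean` and scale `base_sd` (defaults 0 and 1, giving right-skewed
positive marginals with a coefficient of variation near 1.3, typical of MS
intensities), exponentiated to the observed scale. Planted group effects
shift the latent mean of selected features by `effect_size` within-group SD
units in every non-reference group, so the planted truth is defined on the
log scale in interpretable SD units. Correlation blocks are imposed on the
latent Gaussian via the Cholesky factor of the block correlation matrix — a
Gaussian copula on the observed scale, matching what the augmentation module
estimates. Missingness is MCAR (`missing_rate`): with no credible
characterization of how real bile features go missing, no informative
mechanism is invented. Integer mode rounds half away from zero and clamps at zero;
clamping biases moments of low-abundance features, so moment-recovery
checks use features whose mean is well above zero.

What the generator does **not** emulate: batch effects, heteroscedastic
technical noise, informative missingness, non-Gaussian dependence (tail
dependence), or annotation structure among features. Passing tests on these
fixtures therefore demonstrate the pipeline's statistical correctness and
power under idealized conditions, not its performance on any real cohort.

The toy spectrum generator produces Lorentzian peak sums on a ppm grid, a
0.00-ppm reference standard peak, rectangular artifact bumps (emulating
residual water and contrast-reagent signal; deliberately *not* scaled by
dilution), per-sample dilution factors and Gaussian noise. A non-zero
`reference_peak_offset` models a calibration error and therefore displaces
the entire spectrum, which is what `reference_to_standard()` corrects. One
simplification: the reference peak scales with the dilution factor like
every other peak, although a real internal standard is added at fixed
concentration; this keeps "spectrum = dilution × pattern" exact, which the
dilution-recovery checks rely on.

## Analysis scale: why the pipeline log-transforms by default

MS abundance data are right-skewed. On the observed scale of the log-normal
fixture, a planted 1.5-SD latent effect shrinks to roughly 0.6–0.9 SD
because the heavy tail inflates the denominator, and DAPC recovery of a
planted 10-feature panel plateaus around 75–80% of seeds regardless of how
many PCs are retained — the information loss happens in the marginal scale,
before any reducer sees the data. `log_transform()` (natural log, with a
half-minimum pseudocount only when zeros are present) restores the latent
scale, after which recovery is essentially complete. `run_pipeline()`
applies it by default; disable it (`log_transform = FALSE`) for tables
already on a symmetric scale or to generate integer count-scale synthetic
data for proteomics-style tables.

## NMR processing choices

* **Bucketing** uses half-open intervals `[low + i·w, low + (i+1)·w)`
  anchored at the region's low edge (defaults: width 0.01 ppm, region
  0.261–8.757 ppm, giving 849 full buckets plus one truncated bucket that is
  kept). Bucket values are trapezoidal integrals with interpolated
  endpoints, so kept plus dropped buckets exactly telescope to the
  whole-region integral.
* **Exclusions** (defaults: residual water 4.59–4.78 ppm and four iohexol
  contrast regions) drop any bucket that overlaps them at all; clipping
  would create variable-width buckets.
* **Normalization order** is total-area first, then PQN, and the bucket
  table accumulates a *relative* dilution estimate across the two steps
  (total-area contributes `row_total / median(row_totals)`, PQN its median
  quotient). PQN can only identify dilution up to the scale of its
  reference, so recovery is assessed after matching medians.
* **Referencing** picks the maximum intensity inside a ±0.2 ppm window
  around 0 — instrument-software peak-picking rules vary, and the window
  maximum is the simplest deterministic choice — and re-interpolates
  linearly; a flat window warns and applies no shift.
* **Imputation** is fixed to distance-weighted kNN (k = 5 default,
  Euclidean over z-scored co-observed features) as an explicit, testable
  stand-in for an unspecified imputation toolchain.

## Permutation inference

The two-group statistic is the absolute difference of group means,
two-sided by construction. With `choose(n, n1)` arrangements at or below
`exhaustive_limit` (default 50,000) the test enumerates all label
arrangements and the p-value is the exact exceedance fraction (the observed
arrangement counts, so p > 0); above the limit, `n_mc` Monte-Carlo draws
(default 9,999) give the add-one estimate `(b+1)/(m+1)`, which can never be
zero. Tie comparison uses `>= observed − 1e-9·scale` so floating-point
summation order cannot flip structural ties. `differential_features()`
shares one set of label permutations across all features for speed; each
feature's p-value is marginally the standard estimator. Fold-changes use a
pseudocount of half the smallest positive observed value, applied only when
a group mean is zero. Multi-group cohorts are summarized by pairwise
contrasts against the reference (first) group rather than an omnibus
statistic, mirroring how such cohort tables are reported.

## Synthetic-data augmentation

`estimate_moments()` computes per-group sample means, SDs (n−1) and Pearson
correlations; zero-SD features get zeroed correlation rows with a flag.
Moments are per group, not pooled: classifier training needs group-labelled
synthetic samples. `generate_synthetic()` draws from N(μ, D·R·D) per group.
With 5 samples and 2000 features the sample correlation matrix is severely
rank-deficient and numerically indefinite; it is repaired by eigenvalue
flooring at 0 plus a 1e-10 jitter, followed by diagonal renormalization,
and the repair magnitude (minimum eigenvalue, number clipped, clipped mass)
is logged in the cohort's provenance. The default synthetic size is 500 per
group — large enough to train stably, small enough for desk-scale reruns —
and is configurable. Negative decimal draws are kept by default because
truncation would distort the very moments the generator is built to
preserve (an optional clamp exists); integer mode rounds half away from
zero and clamps at 0. No extra noise is added by default: the sample
covariance already embodies measurement noise (an optional `noise_sd`
jitter exists).

## Feature reduction and panels

**DAPC** z-scores features, reduces by PCA (auto rule: smallest PC count
reaching 90% cumulative variance, capped at n − groups; configurable), and
runs LDA on the retained scores. The per-feature contribution is the
eigenvalue-share-weighted sum over discriminant axes of squared
back-projected loadings, normalized to 1 — the established DAPC loading
convention. The selection rule keeps features contributing at least 2%
(configurable), ranked descending, ties broken by feature id. **RF**
importance is permutation importance from a single-threaded, seeded random
forest. **AUC** ranks features by `max(AUC, 1−AUC)` of the raw values, the
direction-free normalized Mann–Whitney statistic with midranks.

Candidate panels are nested top-k prefixes (k = 3…10) of each ranking.
Exhaustive subset search over 162–2042 features is combinatorially
infeasible, and ranked selection naturally implies prefixes; "best 3 to 10
variable combinations" is realized as 8 nested panels per route.

## Training, validation and combo selection

Each panel is z-scored by its training moments (identically at prediction
time). Hyperparameters are tuned by stratified k-fold CV maximizing AUC
when the grid has more than one point; single-point grids skip CV. The NN
is a single-hidden-layer perceptron (grid over hidden sizes {1,3,5} ×
weight decay {0.001,0.01,0.1} by default); BGLM is ridge-penalized IRLS
logistic regression, the fixed-regularization realization of a
weakly-informative prior that keeps separable fits finite; C5TREE is an
information-gain decision tree with a pruning-complexity grid (the defining
elements of the C5.0 family); RF is a probability forest, admitted only
with RF-sourced panels as the reference pairing. AUC uses midranks; the
operating threshold maximizes Youden's J with ties resolved towards higher
specificity, the conservative direction when a single
sensitivity/specificity pair must be reported. Combo selection maximizes
validation AUC with ties broken by smaller panel, then higher sensitivity,
then algorithm name.

**Leakage, deliberately preserved.** The flow estimates moments from the
same real samples later used for validation. Under a true null this leaks:
synthetic data memorizes the noise difference between the groups, and the
winner of ~80 combos is picked by its validation AUC, so null validation
AUCs are inflated well above 0.5. This is inherent to the single-cohort
train-on-synthetic design, and Test 5 is the diagnostic that exposes it (its shuffled-
pipeline AUCs sit visibly above 0.5). For clean null calibration,
`run_pipeline()` accepts an independent `validation` cohort, and the
package's null checks evaluate the winner against an independently drawn
cohort.

## The five robustness tests

All five use the identical midrank-AUC evaluator, so their p-values are
comparable. Tests 1–4 use add-one corrected p-values with n_perm = 999 by
default; Test 5, which refits the entire pipeline per shuffle, defaults to
49 shuffles. Sub-seeds derive deterministically from the master seed.
Test 1 permutes labels against *fixed* scores — it does not refit the
model; the refitting reading of label permutation is exactly what Test 5
provides, and separating the two keeps "score significance" distinct from
"pipeline overfitting". For a single-feature panel, Tests 2 and 3 are by
construction the same procedure and coincide exactly under a shared seed.
Test 4 is expected to yield *large* p-values when no single feature carries
the classification alone.

## Numerical choices and degenerate inputs

* PCA uses a deterministic sign convention (largest-magnitude loading
  positive). Degenerate PCs (relative sdev < 1e-8) are never retained.
* Constant features: DAPC passes them through with zero contribution; PCA
  with scaling errors unless asked to drop them; RF importance gives them
  a noise-floor score; moments flag them.
* Ties everywhere break by ascending feature id; leaderboard ties by the
  documented tie-break chain. Group level order is first appearance, never
  a locale-dependent sort; the first group is the reference and the second
  the positive class.
* All Monte-Carlo p-values are add-one corrected and strictly positive.
* Reruns with identical inputs, config and seed are bitwise identical
  (single-threaded forests, seeded draws, RNG state restored after use).

## Problem sizes used by the test-suite and acceptance script

The suite exercises the full study shapes (129 × 162 cohorts; 5 vs 5 with
2000 features) but scales Monte-Carlo depth to desk size as its own
configuration: single-point tuning grids and 150–500 synthetic samples per
group in end-to-end runs, n_perm = 99–299 for permutation checks, 19–49
shuffles for Test 5, and 20-seed replications for power/calibration
properties. These sizes are stated here as the package's chosen test
conditions; all thresholds they are checked against are fixed in the test
code.

## Known limitations

* The fixture's marginals are a stand-in; nothing here claims to model bile
  chemistry, batch structure, or real missingness mechanisms.
* The Gaussian-copula generator cannot represent tail dependence or
  nonlinear feature relationships; classifiers that exploit such structure
  in real data are not advantaged by this augmentation.
* The C5.0-family tree is an information-gain, cp-pruned realization, not a
  line-for-line port of the proprietary implementation; the BGLM is a
  fixed-ridge realization of weakly-informative priors, not full posterior
  inference.
* Validation-on-the-training-cohort leakage is reproduced by design; any
  headline AUC from this flow on a single cohort should be read together
  with Test 5 and, ideally, an external validation cohort.
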