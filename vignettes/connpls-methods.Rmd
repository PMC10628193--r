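---
title: "Behavioural PLS for brain connectomes: models, inference, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioural PLS for brain connectomes: models, inference, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(connpls)
```

This vignette is the package's own account of its science: the model and its
assumptions, the tunable parameters with their defaults and units, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the design decisions made where the design was genuinely open. It states
no empirical result that the test suite does not itself compute.

## 1. The analysis problem

A cohort of n subjects contributes two blocks: an edge block **X**
(subjects × E), holding Fisher-z-transformed Pearson correlations between
the time courses of every pair of brain parcels, and a behaviour block
**Y** (subjects × P). E grows quadratically with the parcellation —
n(n−1)/2 unique edges, e.g. 30,135 for 246 regions — so E ≫ n is the normal
regime. The scientific question is whether a small number of *latent
dimensions* couple interindividual variation in connectivity to
interindividual variation in behaviour, and whether those dimensions
generalize: to held-out subjects, to independent cohorts, to molecular
annotation maps, and to clinical classification.

### Canonical edge order

All vectorized connectivity uses one fixed bijection: the strict upper
triangle, row-major, 0-based — (0,1), (0,2), …, (0,n−1), (1,2), …. The
source study does not state its internal ordering; since every result is
order-covariant, any fixed convention is acceptable, and fixing one makes
saved loading vectors portable (`edge_index()`, `edge_pair()`).

## 2. Behavioural PLS

Both blocks are standardized columnwise; the cross-correlation matrix
R = YᵀX/(n−1) is decomposed by SVD, R = U S Vᵀ. LV k pairs the behavioural
salience u_k with the edge salience v_k (both unit-norm), carries singular
value s_k, and explains s_k²/Σs² of the cross-block covariance. Composite
scores are unscaled projections X v_k and Y u_k; *loadings* — the reported
feature-importance surface — are Pearson correlations between raw features
and their own block's composite.

Design choices made here, in places the source material leaves open:

- **Cross-correlation, not covariance.** R is computed on standardized
  blocks. This is the standard behavioural-PLS formulation of the cited
  methods literature and makes `covariance_explained` scale-free.
- **Unscaled projection.** Whether saliences should be rescaled by singular
  values before projection is unstated in the available material; composite
  *correlations* are invariant to per-LV rescaling, so the simpler unscaled
  projection is used.
- **Sign convention.** An LV is defined up to a joint sign flip of
  (u_k, v_k). At fit time, and after every resample alignment, signs are
  flipped so the largest-magnitude entry of u_k is positive. The convention
  is idempotent, and every reported quantity is invariant to joint flips.
- **Loadings vs saliences.** Loadings (feature–composite correlations) are
  the importance surface used for thresholding and region summaries;
  saliences remain available on the model object.

## 3. Nonparametric inference

**Permutation test (`permutation_test_lvs`).** Rows of Y are permuted
uniformly (X fixed), the model refit, and permuted singular values matched
to observed LVs *by rank order* — no Procrustes rotation. Rank matching is
the simplest defensible choice for per-LV covariance tests with FDR across
LVs; a rotation-based null is a possible extension but not required by the
tested claims. p-values use the add-one rule (1 + #exceed)/(n_perm + 1) and
are therefore never exactly zero; q-values are Benjamini–Hochberg (the
generic "FDR correction" of the field). Default n_perm = 1000.

**Bootstrap (`bootstrap_loadings`).** Subjects are resampled with
replacement; each replicate's LVs are sign-aligned to the original by the
inner product of behavioural saliences; per-feature loading standard
deviations and z = loading/SD are accumulated. Replicates in which a
resampled column is constant are skipped for the affected features and
counted. Default n_boot = 1000.

**Cross-validation (`cross_validate_pls`).** Repeated k-fold (default
10-fold × 200 repetitions). *Everything estimated from data — confound
regression coefficients, centering, scaling — is fitted on the training
folds and applied unchanged to the test fold*, which is then projected onto
the training saliences; the statistic is the correlation between test-fold
edge and behaviour composites, averaged over folds × repetitions (the
per-fold-then-average reading of the protocol; pooling across folds is the
unchosen alternative). Significance comes from rerunning the whole CV with
Y rows shuffled. Because each permutation is itself a repeated CV, the
default permutation count is 100 with a single repetition inside each
permutation — a documented cost/precision trade-off; the add-one formula
keeps p ≥ 1/101.

## 4. Preprocessing and the leakage guard

`fit_residualizer`/`apply_residualizer` implement per-column OLS on
[1 | confounds], storing coefficients and the training residuals' mean and
sd. Categorical confounds (sex, handedness) are numerically coded by the
caller; each block gets its own residualizer (the only coherent reading of
a shared-confound design with different column spaces). Residuals are
orthogonal to the confounds on the training set; on held-out data only
stored parameters are applied. Quantile normalization
(`quantile_normalize`) maps each column by rank to Φ⁻¹((rank − 0.5)/n),
ties receiving the mean of their tied quantile positions (tie handling is
unstated in the source material; averaging is the standard choice).

The leakage property this buys is tested directly: on cohorts whose only
shared structure is confound-driven, in-fold residualization yields CV test
correlations centred on zero, whereas the unresidualized analysis produces
spurious "significant" LVs at far above the nominal rate.

## 5. The synthetic world

`generate_cohort` plants exactly the structure PLS assumes: a latent score
z ~ N(0,1) per subject, X = a·z·uᵀ + confounds + noise and
Y = a·z·vᵀ + confounds + noise, with unit-norm u, v supported on
configurable fractions of features, and a = σ·sqrt(ρ/(1−ρ)) so that
corr(Xu, Yv) = ρ in expectation. Two calibration choices matter:

- **Confound directions are orthogonal to the planted saliences.** Confound
  effects (Q = 4 by default: two continuous, two binary, mirroring
  age/motion and sex/handedness) are applied along random directions
  projected orthogonal to u and v. Contamination then inflates spurious
  cross-block covariance — which the leakage and contamination tests rely
  on — without biasing the planted-strength calibration, keeping it exact
  in expectation rather than approximately so.
- **Defaults mirror the motivating study's stated world**: 687 subjects,
  246 regions, 36 behavioural measures, planted strength 0.5 (the reported
  composite correlation), edge support 20% (the reported significant-edge
  fraction), behaviour support 75% (27 of 36 measures significant).

`generate_two_group_cohort` shifts group 1's latent scores by
`group_shift`, with within-group spread `latent_sd` (default 1). A note on
an internal tension in the build contract: its separability example pairs
"shift 3" with "groups linearly separable", which cannot hold when the
within-group latent spread is 1 (the Bayes accuracy of that world is ≈0.93,
and sample Bayes-rule accuracies dip to 0.90). The generator therefore
exposes `latent_sd`; the acceptance test instantiates the *separable* world
(shift 3, latent_sd = noise_sd = 0.3, d′ ≈ 7), and the heterogeneous
default remains realistic for clinical cohorts.

`generate_annotation_map` draws from a Gaussian process over region
centroids (squared-exponential kernel, length scale in mm, default 20) and
standardizes the map. What the generator does *not* emulate: hemodynamics,
non-Gaussian behavioural marginals (supported separately via quantile
normalization), site/batch structure, heavy-tailed motion artefacts,
spatially structured edge noise, or receptor biochemistry. A green test
therefore establishes correctness of the statistical machinery on its
stated assumptions, not robustness to every failure mode of real data.

## 6. Spatial surrogates

Correlating a region-importance map with an annotation map needs a null
that preserves spatial autocorrelation — neighbouring parcels are not
exchangeable. A volumetric parcellation with subcortex rules out
sphere-rotation nulls, so the package uses variogram-matching surrogates
over Euclidean centroid distances: permute the map's values, smooth with a
truncated Gaussian kernel (truncation at the 70th distance percentile),
and rank-remap to the original value multiset — every surrogate is an
exact permutation of the observed values. The kernel scale is selected
once per map by minimizing the squared distance between surrogate and
source variograms (25 equal-count distance bins, 10 training
permutations).

One numerical finding shaped the defaults: scale selection is the fragile
step. With 5 training permutations the selected kernel is noisy and often
undersized, and the resulting null rejects true-null spatial correlations
at well above the nominal 5% rate; with 10 permutations a dedicated
calibration study (400 independent smooth map pairs per condition,
100-region clouds, 20 mm process) measured a false-positive rate of 0.055
at α = 0.05 for the matched scale — essentially nominal — while deliberate
oversmoothing by factors 1.15/1.3/1.45 drove the test conservative
(0.040/0.033/0.025). The defaults are therefore 10 training permutations
and strict variogram matching (`oversmooth = 1`, exposed as an explicit
conservativeness option); the acceptance suite re-measures the resulting
false-positive rate over 500 independent map pairs. A related limitation:
at the shortest lags the smoothed-permutation family cannot reproduce the
source variogram to within 20% in every fine bin; the test suite asserts
the achievable contract (exact multiset preservation, close tracking where
naive permutations are flat, ~20% mean deviation).

Empirical p-values are two-sided with the add-one rule; batches of maps are
FDR-corrected. Spearman correlation is the default (the protocol's stated
method) with Pearson exposed as an option, mirroring an unresolved
discrepancy in the source material between its methods text and figure
captions.

## 7. Prediction and classification

The contribution here is the harness, not the solver: nested
cross-validation (hyperparameters chosen by an inner loop strictly inside
each outer training set), feature scaling fitted on outer-training data
only, repeats averaged per subject, and label-permutation significance.
Masks may be *externally fixed* (the intended use: a significant-edge mask
from an independent discovery cohort, applicable globally) or
*data-derived*, in which case they must be derived upstream on independent
data; the mode is recorded in the report.

Because no SVM implementation exists in the supported dependency set, the
package provides compact kernel machines: squared ε-insensitive SVR
(linear kernel, primal, ε = 0.1) and a squared-hinge (L2) SVM with RBF
kernel in the dual representation, both solved by BFGS with analytic
gradients. These are standard large-margin formulations with the same
C/γ semantics as the usual quadratic-programming solvers; at the cohort
sizes involved (n ≤ a few hundred) the smooth formulations are accurate
and fast. Default grids follow the full-size protocol: C ∈ 0.1…1 step 0.1
for SVR; C ∈ 2⁻⁵…2¹⁵, γ ∈ 2⁻¹⁵…2³ in ×4 steps for the SVM; 10 outer and
10 inner folds; 100 repetitions; 1000 permutations. Inner-loop selection
criteria (Pearson r for SVR, accuracy for SVM) are stated choices where
the protocol says only "prediction performance". AUC is computed from
per-subject decision values averaged over repetitions (the per-repetition
alternative is noted but not used). Classification reports flag mean
accuracy above 70% as "meaningful", following the protocol's stated
threshold.

## 8. Numerical and policy details

- Correlations use the sample (n−1) normalization throughout.
- |r| = 1 in Fisher's transform is a hard error by default (perfect
  correlations usually mean duplicated regions); clipping at 1 − 10⁻⁷ is
  available behind a flag.
- Missing behavioural values are rejected by default; column-mean
  imputation is available behind a flag with a warning.
- Constant columns are flagged and propagated as zeros rather than NaNs.
- Subject alignment between blocks is by id, never by row position.
- Percentages in mask summaries are rounded half-up to two decimals for
  report parity with printed literature values.
- One master seed drives derived child streams per permutation, bootstrap
  replicate, CV repetition, and surrogate, so runs are bit-reproducible
  and the add-one p-value floors are exact.
- Pipeline configuration is JSON (no YAML parser in the supported
  dependency set); every artifact embeds the config, seed and package
  version.

## 9. Known limitations

- Desk-scale test worlds use tens of regions, not 246; runtimes of the
  full-size protocol (200 CV repetitions × 1000 permutations) are hours,
  and the test suite documents where it scales counts down.
- The spatial-null oversmoothing constant was validated on
  squared-exponential Gaussian-process worlds; maps with qualitatively
  different autocorrelation (e.g. strong anisotropy) may calibrate
  differently.
- Regression-mode PLS (deflation), sparse PLS, CCA, and multi-class
  classification are out of scope.
- The two-group generator produces edge-level data directly; it does not
  simulate time series for the classification cohort.
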