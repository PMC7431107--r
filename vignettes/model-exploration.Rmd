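---
title: "Methods: radiomics feature extraction and pipeline exploration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomics feature extraction and pipeline exploration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radexplore)
```

`radexplore` automates the four stages of a binary-outcome radiomics
study: feature extraction from image/ROI volumes, preparation of the
case-by-feature matrix, exhaustive enumeration and cross-validation of
modeling pipelines, and clinical-statistics reporting. This vignette is
the package's account of the science behind each stage: the procedures,
their assumptions, the tunable parameters, and the choices made where a
convention had to be pinned down.

## Feature extraction

Each case is a folder holding one or more NIfTI image series plus a
binary ROI mask aligned to them. Features are computed per series and
prefixed with the series name; shape features depend only on the mask and
appear once per case. All definitions follow the IBSI reference
formulations.

**Quantization.** Texture matrices require discrete gray levels. The
package uses a fixed bin count (default `n_bins = 32`), equal-width over
the in-ROI intensity range, with the maximum intensity assigned to the
top bin. Fixed-count binning keeps the matrix dimensions bounded
regardless of intensity units and makes texture features invariant to
adding a constant to the image, because the bins shift with the data
range. A constant ROI collapses to a single level. The alternative —
fixed bin *width* — preserves absolute intensity meaning but makes the
matrix size data-dependent; it is deliberately not offered, so results
are always comparable across cases.

**GLCM.** Pairs of gray levels at offset distance 1 (configurable) over
all 13 unique 3-D directions, accumulated symmetrically (each pair in
both orders), *summed* over directions, then normalized once. Summing
counts before normalizing — rather than averaging per-direction feature
values — is one canonical, testable choice; for distance-1 offsets on a
connected ROI the two differ little, but the convention is pinned and
stated here because published extractors vary.

**GLRLM.** Maximal runs of equal level along each direction, summed over
the 13 directions. Run percentage divides total runs by
(ROI voxels × number of directions), so each direction contributes a
value in (0, 1]. Internally, voxels are grouped into lines using the
integer key `k·v − (v·d)d` (with `k = |d|²`), which is exact arithmetic —
floating-point projections are unreliable line identifiers for diagonal
directions.

**GLSZM.** Zones are connected components of equal level under
26-connectivity (8-connectivity for in-plane ROIs), found by
frontier-expanding flood fill. The zone decomposition partitions the ROI,
an invariant the tests assert against an independent graph-components
oracle.

**2-D versus 3-D.** Thick-slice MR lesions often occupy a single slice.
With `mode = "auto"` (default) texture geometry is 3-D when the mask
spans more than one slice along the third axis and in-plane 2-D (4
directions, 8-connectivity) otherwise, so near-planar ROIs are not
dominated by degenerate through-plane runs. Both modes can be forced.

**First-order and shape.** Percentiles (10th, 90th, quartiles for the
interquartile range) use linear interpolation between closest ranks —
the convention must be pinned because the 10th-percentile and IQR
features are typically reported verbatim. Variance, standard deviation,
skewness, and kurtosis (non-excess) use the population (divide-by-N)
convention, matching IBSI. Volume is voxel-counting times voxel volume;
surface area counts exposed voxel faces scaled by the physical face
areas. Face counting overestimates the area of smooth shapes, so
sphericity `π^(1/3)(6V)^(2/3)/A` of a voxelized sphere sits visibly below
1; the tests bound it instead by the voxel-solid maximum `(π/6)^(1/3) ≈
0.806`, attained by a cube. The default feature set numbers 51 per
single-series case (6 shape + 14 first-order + 11 GLCM + 10 GLRLM + 10
GLSZM); the exact composition of any given published "N features" count
depends on the extractor configuration and is not a target here.

## Data preparation

`load_table()` reads the CSV dialect (first column case index, a `label`
column of 0/1, all other columns numeric features) and audits every cell:
empty/NA, non-numeric text, and infinite values are recorded in a
validity report with their reason rather than silently imputed.
Categorical columns are rejected with a message asking for numeric
encoding — silent dummy-coding changes the feature space under the
user's feet. `drop_invalid()` removes flagged cases or flagged features,
logging each removal.

**Stratified split.** The training count per class is the nearest
integer to `(1 − test_fraction) × class size` (R's round-half-to-even),
with membership chosen by a seeded within-class shuffle. This per-class
rounding convention is the one that reproduces e.g. a 68/184 cohort at a
0.7 training fraction splitting to 48 + 129 = 177 training and 75 test
cases.

**Balancing** applies to training data only; the API refuses tables
flagged as test, because balancing a test set would corrupt the very
estimate it exists to provide. Downsampling subsamples the majority
without replacement; upsampling resamples the minority with replacement;
SMOTE synthesizes minority points `x + u(x_nn − x)` with
`u ~ Uniform(0,1)` and `x_nn` among the `k = 5` nearest minority
neighbors (the method's canonical neighborhood size, configurable);
SMOTETomek follows SMOTE by removing both members of every Tomek link
(cross-class mutual nearest neighbors), so final counts can differ
slightly from exact balance.

## Pipeline enumeration and cross-validation

A pipeline is one choice of normalizer (`zscore`, `minmax`, `mean`),
reducer (`pcc`, `pca`, `none`), selector (`anova`, `rfe`, `relief`,
`none`), feature count, and classifier (ten kinds, from logistic
regression to multilayer perceptron). `enumerate_pipelines()` builds the
full Cartesian product in stable normalizer-major order, so a run's grid
is reproducible and its size is exactly the product of the menu sizes.

Conventions pinned per stage:

* **Mean normalization** is `(x − mean)/(max − min)` — the conventional
  reading of the term. A zero-spread feature maps to all zeros and is
  logged, never NaN.
* **PCC filter**: feature pairs are scanned in a seeded random order;
  whenever a surviving pair has |Pearson r| > 0.9 one member is removed,
  chosen by the seeded stream. "Remove one at random" is inherently
  order-dependent, so determinism comes from the seed, not from a
  canonical scan order; the guaranteed postcondition is that no surviving
  pair exceeds the threshold.
* **ANOVA** ranks by the two-group F statistic (identically the squared
  pooled-variance t). Zero within- and between-group variance gives F = 0;
  zero within- with nonzero between-group variance ranks first (+Inf) and
  is logged.
* **Relief** is the classic single nearest hit/miss algorithm on features
  rescaled to [0, 1], visiting every case in order by default (no
  sampling noise); `k_neighbors > 1` gives the ReliefF extension, and
  subsampling (`n_iterations < n`) is seeded.
* **RFE** repeatedly drops the smallest-|coefficient| feature of a linear
  base model fit on standardized columns (LDA scaling by default,
  logistic coefficients as an option) until the requested count remains.
* **LASSO as a classifier** means L1-penalized logistic regression at a
  pinned `lambda = 0.05`; classifier hyper-parameters are library
  defaults frozen in `classifier_defaults()` and recorded in the run
  manifest. AdaBoost is discrete two-class boosting over depth-1 stumps,
  implemented in-package.

**Cross-validation.** Folds are stratified: each class is shuffled by the
seeded stream and dealt round-robin, so every fold preserves the class
ratio up to one case. Inside each fold, *every* fitted statistic — the
normalizer's location/scale, the correlation filter's kept set, PCA
loadings, the selector ranking, and the classifier — is fit on the k−1
training folds only and applied frozen to the held-out fold.
Normalization statistics are computed within folds rather than once on
the full training set: the difference is small but it is exactly the kind
of quiet leakage the tests guard against (held-out scores must equal an
independent refit on the training folds alone). The validation summary is
the mean of the per-fold AUCs; its SE is the across-fold standard
deviation divided by √k. Pooled held-out scores are also kept (every case
is held out exactly once) for pooled validation statistics; ranking uses
the per-fold average.

## Evaluation and selection

AUC is computed by the Mann–Whitney identity with ties counting ½ —
identical to the trapezoidal area under the empirical ROC. Confidence
intervals are percentile bootstrap with 1000 stratified case resamples
(each class resampled within itself, so no resample is degenerate and no
redraw rule is needed); the method is the simplest defensible default
where no analytic interval is prescribed. Accuracy, sensitivity, and
specificity are reported at the cutoff maximizing Youden's J on the
*training* scores, reused verbatim for validation and test data — one
fixed, testable rule matching common clinical practice; ties take the
lowest cutoff.

Models are ranked by mean validation AUC, ties broken in favor of fewer
features. Within the winning component combination, the
one-standard-error rule re-chooses the feature count: the smallest n
whose mean AUC is within SE(argmax) of the maximum, never exceeding the
argmax. The test set is scored once, for the final selected model only;
`evaluate_model()` refuses test scoring for other specs unless forced,
mirroring the single-use contract of a held-out dataset.

## What the synthetic data does and does not show

`make_table()` draws informative features `Normal(±d/2, 1)` by class and
noise features `Normal(0, 1)`, optionally with an equicorrelated
near-duplicate block to exercise the redundancy filter; `make_phantom()`
builds sphere/box lesions with constant, checkerboard, gradient, or
Gaussian-noise textures. Both are pure functions of their spec, seed
included. The defaults encode the reference conditions used throughout
the tests: 100 cases per class, 50 features with 5 informative at
standardized mean difference 1.5 (a strong but realistic radiomics
effect), and an imbalanced 68/184 preset for split and balancing checks.

These generators emulate the *statistical* structure the pipeline
machinery must handle — class overlap, redundancy, imbalance — not real
data. They are Gaussian, independent across cases, and free of scanner
effects, segmentation noise, non-linear class boundaries, and
feature-feature dependence beyond the planted block. A pipeline passing
the recovery test is therefore known to find linear mean-shift signal
without leaking information; nothing more is claimed about clinical
performance.

One statistical subtlety is worth stating because it shaped the no-signal
check. The across-fold SE of a cross-validated AUC measures fold-to-fold
variation *within one dataset*; it does not include the dataset-level
variance of chance feature–label association. With 200 cases and 50 noise
features the most label-correlated feature reaches |r| ≈ 0.19 by chance
alone, and a selector will find it in every fold, pushing a single
dataset's CV AUC as far as ~0.6 with a small fold SE — with no leakage
anywhere. The package's no-signal fixture is therefore sized (100 cases,
20 features) so that the fold SE honestly dominates this effect, and the
chance-level assertion (within 3 SE of 0.5) is made on that fixture.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use deliberately modest
sizes, chosen as the smallest at which each property is sharply testable:
4³ phantoms for brute-force texture oracles, 60–200-case tables for the
selector and cross-validation checks, a 40-pipeline grid (2 selectors ×
2 linear classifiers × 10 feature counts) for the recovery run, and 200–
1000 bootstrap resamples. Degenerate inputs are contracts, not surprises:
empty masks error, constant features normalize to zero with a log line,
constant ROIs yield single-level matrices with zero gray-level variance,
and every stochastic component takes an explicit seed and restores the
caller's RNG state.

## Known limitations

* Only binary outcomes; no regression, multi-class, or survival targets.
* No filtered-image (wavelet / Laplacian-of-Gaussian) feature families,
  ROI segmentation, registration, or DICOM reading — inputs are aligned
  NIfTI volumes.
* Texture code is pure R, sized for lesion-scale ROIs (thousands of
  voxels), not whole-organ masks.
* The PCC filter's survivor set depends on its seed by construction; two
  seeds can keep different (equally valid) representatives of a
  correlated cluster.
* Grid-search of classifier hyper-parameters inside folds is limited to
  the pinned per-classifier override lists; there is no nested search UI.
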