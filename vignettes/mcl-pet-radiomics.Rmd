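---
title: "PET radiomics and metabolic risk in mantle cell lymphoma: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PET radiomics and metabolic risk in mantle cell lymphoma: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mclrad)
```

## Scope

`mclrad` implements an end-to-end [18F]FDG PET radiomics analysis for outcome
prognostication in mantle cell lymphoma (MCL): semiautomatic metabolic tumour
volume (TMTV) segmentation, first-order SUV statistics and 16 grey-level
co-occurrence (Haralick) texture features in 3D, ComBat harmonization of
feature tables across scanners, a majority-vote "metabolic risk" score built
from dichotomized SUVmean and Entropy, MIPI/MIPI-b prognostic indices and
their metabolic-risk-modified variants, Kaplan-Meier / log-rank / Cox
survival analysis, and multilayer-perceptron (MLP) prediction of 2-year
progression-free survival (PFS). Because no patient-level imaging cohort of
this kind is public, the package ships a synthetic PET cohort generator with
fully known ground truth; every stage is validated against that ground truth
and against independently coded oracles.

## Segmentation

Lesions are segmented by fixed-fraction SUVmax region growing: given a seed
voxel, the threshold is `fraction x` the current region's maximum SUV
(default fraction 0.41, the threshold recommended for lymphoma TMTV), the
region is the seed's connected component of voxels at or above the
threshold, and the threshold is recomputed from the grown region's maximum
until a fixed point is reached. Growing continues from the region's hottest
voxel, which makes the result independent of where inside a lesion the seed
was placed (and resolves the degenerate `fraction = 1` case to the argmax
voxels). Design choices:

* **Connectivity** is 26-neighbour by default (the most permissive 3D
  scheme, matching common PET tools); 6-connectivity is available.
* **Background floor** (default SUV 1.0) is applied to *seed validation
  only*: a seed below the floor is rejected as background. We deliberately
  do not apply the floor during growth, because a fixed absolute floor would
  break the scaling equivariance of the fractional threshold (multiplying a
  volume by `c > 0` must not change the mask). Leakage into background is
  instead avoided by the contrast between lesions (SUVmean >= 3 by default in
  the generator) and background (~1.0 +- 0.12).
* The TMTV is the union of per-seed masks; touching lesions merge and
  components are relabelled. Total volume is voxel count x voxel volume.
* Externally delineated masks are accepted via `as_tmtv_mask()` as an
  alternate input path (manual, CT-aided delineations).

## Radiomic features

First-order features are SUVmax, SUVmean, SUVpeak, TMTV (mL), and TLG =
TMTV x SUVmean (an exact product, asserted bit-wise in the tests). SUVpeak
is the maximum over masked voxels of the mean SUV in a 1 mL sphere centred
on the voxel; the sphere is the set of voxels whose centres fall within the
sphere radius (6.2 mm), clipped to the grid. For the default 5.5 x 5.5 x
3.3 mm spacing this is a 7-voxel neighbourhood.

Texture features are computed from 3D grey-level co-occurrence matrices:

* **Quantization**: fixed bin *number* over the masked SUV range, default
  G = 64 (`level = min(G, floor(G(x - min)/(max - min)) + 1)`); a constant
  region maps to level 1. The bin count is configurable; note that absolute
  Entropy values (and hence any absolute Entropy cutoff such as 3.5) depend
  on it, which is why the pipeline offers cohort-specific recomputation of
  cutoffs (below).
* **Co-occurrence**: 13 canonical direction offsets (unique 3D neighbour
  directions up to sign), interpixel distance 1 (configurable), ordered
  pairs with both endpoints in the mask, symmetrized by adding the
  transpose. Offsets live in voxel index space; physical anisotropy is
  ignored, as in the common radiomics feature libraries.
* **Validity**: a direction is used only if it contributes at least 20
  pixel pairs (configurable); invalid directions are excluded from the
  arithmetic mean over directions. If no direction is valid the features
  are undefined and an error names the rule.
* **The 16 features**: Entropy, Homogeneity (inverse difference), Contrast,
  Correlation, Angular second moment, Difference entropy, Difference
  variance, Inverse difference moment, Sum average, Sum entropy, Sum
  variance, Cluster prominence, Cluster shade, Maximum probability, and the
  two Informational measures of correlation, in their standard
  Haralick/IBSI forms. All entropies use log base 2 by default
  (configurable); `p log p` terms are evaluated only over
  positive-probability cells (the exact limit), never epsilon-padded. IMC2
  is computed base-invariantly (its exponent uses entropies in nats).
  Degenerate single-level matrices define Correlation = 1 and IMC1 = 0.

Every feature is checked against an independently coded literal-formula
oracle to 1e-10, and the co-occurrence counts against a brute-force
enumeration of all voxel pairs, on over a hundred random masked volumes.

## ComBat harmonization

Scanner batch effects are removed at the feature level with parametric
empirical-Bayes ComBat: each feature is standardized against its grand
(batch-size-weighted) mean and pooled variance; per-batch location and scale
parameters are estimated and shrunk across features (normal prior on
location, inverse-gamma on scale) by the standard iterative solver
(convergence `1e-6`, at most 500 iterations); adjusted values are mapped
back to the grand location/scale. The fit/apply split allows a serialized
model (JSON) to be reapplied to new rows from the same batches. Covariate
protection is available but off by default. The implementation agrees with
the reference genomics implementation to ~1e-9 on identical input.

Two properties worth noting. First, ComBat apply is an affine map per
(batch, feature); applying the *same* model twice is therefore not a no-op,
and even refit-and-apply leaves an empirical-Bayes shrinkage residual of a
few percent — the tests assert that a second fit+apply pass changes values
by an order of magnitude less than the first pass removes, which is the
meaningful convergence property. Second, on a genuinely batch-free cohort
ComBat is *near*-identity (mean absolute change below 0.1 pooled SD), but
residual location noise of O(0.05 SD) can still flip the risk category of
the 1-4% of patients who sit closest to the cutoffs; the pipeline test
bounds this at 5%.

## Risk models

MIPI and MIPI-b are computed from their published coefficients, exposed in
`mipi_constants()` so they are auditable and overridable:
`0.03535 age + 0.6978 [ECOG >= 2] + 1.367 log10(LDH/ULN) + 0.9393 log10(WBC per 1e6/L)`,
plus `0.02142 Ki-67(%)` for MIPI-b; cutpoints 5.7/6.2 (MIPI) and 5.7/6.5
(MIPI-b) give the low/intermediate/high categories.

Metabolic risk is a majority vote over dichotomized SUVmean and Entropy
(default cutoffs 3.55 and 3.5): high if both exceed their cutoffs, low if
both are at or below (ties at the cutoff count as below), intermediate
otherwise; the two-category model collapses intermediate into low.
MIPI-m/MIPI-bm shift the MIPI/MIPI-b category by +1 for high metabolic risk
(capped at 3) and -1 for low (floored at 1).

## Survival analysis and cutoffs

Kaplan-Meier curves, log-rank tests and Cox hazard ratios are computed via
the `survival` package (product-limit estimator with events processed
before censorings at tied times; Breslow tie handling for Cox; Wald
confidence intervals; two-sided p-values, no multiplicity correction). The
median is the smallest event time with S(t) <= 0.5. ROC dichotomization
uses the rank-statistic AUC (ties counted half) and picks the cutoff
maximizing Youden's J over midpoints between adjacent sorted unique values,
breaking ties towards higher sensitivity. Absolute cutoffs do not transfer
across quantization settings, so `pipeline_config(recut = TRUE)` recomputes
them per cohort. Two recut modes are provided. `recut_method = "roc"`
mirrors the study (Youden-optimal against the 2-year PFS endpoint), but
because the cutoffs are optimized on the same outcomes the log-rank test is
then applied to, the downstream test is anticonservative: on zero-effect
synthetic cohorts (n = 500) the 3-category log-rank rejected at the 5%
level in about 24% of 100 simulations. `recut_method = "median"`
dichotomizes at the cohort medians, is outcome-independent, and keeps the
test calibrated; it is what the package's end-to-end power checks use, and
what we recommend whenever the dichotomization and the survival test are
performed on the same cohort.

## Prediction

Feature screening uses Pearson or tie-corrected Kendall tau-b correlations
and univariate binary logistic regression (Wald CIs; complete separation is
flagged, never silently reported), followed by forward selection on the
likelihood-ratio test at entry p <= 0.05. The 2-year PFS classifier is a
single-hidden-layer feed-forward network with softmax output (`nnet`,
default 4 hidden units, weight decay 1e-3), run over 5 repetitions of
random 70/30 train/validation splits; inputs are standardized on the
training split only, and splits are stratified by outcome so both classes
appear on each side. Validation AUC and train/validation accuracies are
reported per repetition with median-and-range summaries. `nnet`'s hidden
activation is the logistic sigmoid rather than the hyperbolic tangent; the
two parameterize the same model family up to an affine transform of the
weights, and all behavioural checks (near-perfect AUC on separable data,
chance AUC under label permutation) are activation-agnostic.

## The synthetic cohort generator

The generator emulates the study conditions: cohorts of 107 patients by
default, voxel size 5.5 x 5.5 x 3.3 mm, five scanners with the study's
43/41/10/10/3 patient counts (assigned exactly proportionally and shuffled,
so every batch stays harmonizable), and a 2-year progression rate
calibrated to 37.2%. Per patient it draws a mean lesion SUV (default range
3-6, bracketing the study's mean SUVmean of 3.78) and an intralesional
subregion scale (correlation length, 4-24 mm); lesions (1-3, semi-axes
10-20 mm — the paper reports no lesion-count or size distribution, so these
are desk-scale choices typical of nodal MCL) are ellipsoids on a smooth
background of ~1.0 +- 0.12 SUV.

Lesion interiors are *subregion mosaics*: a correlated random field at the
patient's subregion scale is sliced into equal-probability plateaus of
distinct uptake (spread +-30% of the lesion mean by default), one level per
metabolic subregion, plus a smooth residual field (SD 0.1 SUV). The number
of plateau levels is `1 + min(7, floor(diameter / scale))`, so short scales
give many distinct uptake levels — the image-domain analogue of subclonal
metabolic heterogeneity — and scales at or beyond the lesion diameter give
a single level; infinite scale with zero residual SD is the exactly
constant homogeneous limit. This construction is deliberate: a single-scale
Gaussian field is *invisible* to co-occurrence Entropy under fixed-bin-number
quantization (normalizing by the masked range cancels smoothness almost
exactly; we measured a 0.06-bit entropy difference between near-white and
near-constant fields), whereas discrete multi-level structure moves Entropy
by 2-3 bits across the scale range and makes the measured feature track the
generative heterogeneity (r ~ 0.55 through the full segmentation + texture
chain). Scanner batch effects are injected at the *feature* level (where
ComBat operates) as per-batch location/scale distortions.

Outcomes: a per-patient heterogeneity score in [0, 1] (linear in
correlation length, 1 = most heterogeneous) stands in for true Entropy.
Event times are exponential with hazard
`baseline x exp(log_hr x risk_step)`, where `risk_step` in {0, 1, 2} counts
which of true SUVmean / heterogeneity exceed their range midpoints
(defaults: baseline log(2)/39.4 per month, i.e. a 39.4-month median PFS in
the lowest-risk group; log hazard ratio log(2.597)/2 per step, the per-step
value implied by the study's three-category model). When a logistic
coefficient vector is supplied (default: odds ratios 1.272 per SUVmean unit
and 5.070 per heterogeneity unit, intercept auto-calibrated to a 37.2%
marginal 2-year progression probability), the event time is drawn from the
same exponential *conditioned* on a Bernoulli 2-year-progression draw from
the logistic model, so that P(event <= 24 months) equals the logistic
probability exactly while remaining exponential within each side; with
`outcome_logit_coeffs = NULL` the draw is pure proportional hazards (used
for hazard-ratio recovery and power simulations). Censoring is independent
exponential with rate tuned to the target censored fraction (default 20%).
A single master seed derives per-patient substreams, so cohorts are
reproducible under partial regeneration; the clinical table (age 64.5 +-
10.8, ECOG with ~6.5% >= 2, log-normal WBC and LDH, beta-scaled Ki-67, Ann
Arbor and blastoid frequencies as observed in the study cohort) is drawn
from its own substream.

What the generator does *not* emulate: PET count noise and reconstruction
artefacts, respiratory motion, partial-volume effects, physiologic uptake
that could confuse segmentation, and any dependence of outcome on clinical
covariates (ECOG/WBC/LDH/Ki-67 are pure noise with respect to outcome by
default). Passing tests therefore demonstrate the correctness and
statistical behaviour of the analysis chain, not clinical performance on
real scans.

## Problem sizes used in the validation suite

The test suite validates the texture stack on >= 100 random volumes up to
8^3 voxels with up to 8 grey levels against brute-force oracles; logistic
recovery at n = 5000 with 200 null replicates for CI coverage; Cox
hazard-ratio bias over true HR in {1, 1.5, 2.285, 4} with 200 replicates of
n = 1000; ComBat recovery at n = 200 per batch; MLP behaviour at n = 300;
and end-to-end power over 25 + 25 single-lesion cohorts of n = 500 (28 x 28
x 18 voxel fields of view) with per-step log hazard ratio 0.8 versus 0.
These sizes were chosen so the whole suite runs on a desktop in minutes
while keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* Absolute Entropy values (and the 3.5 cutoff) are quantization- and
  log-base-specific; cross-cohort transfer of cutoffs requires identical
  feature settings, otherwise use `recut = TRUE`.
* The ROC-optimal cutoff convention (Youden's J at midpoints) is one of
  several defensible choices; the study does not state which convention
  produced 3.55/3.5.
* Whether the published hazard ratios came from univariate indicator Cox
  fits is not stated; univariate fits are the natural reading and are what
  `cox_hr()` provides.
* Non-parametric ComBat and longitudinal variants are out of scope.
* The MLP is deliberately small (one hidden layer); no hyperparameter
  search or calibration analysis is performed.
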