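---
title: "Methods: facial-behavior coordination features and diagnosis prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: facial-behavior coordination features and diagnosis prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Autism spectrum disorder is diagnosed from observable behavior, and brief
naturalistic conversations carry enough signal that both trained clinicians
and automated pipelines can predict diagnostic status well above chance from
a few minutes of silent face video. `facesync` implements the analysis side
of such a pipeline. It does **not** fit face models to video: its inputs are
per-frame face-model fits (a head-rotation matrix and an expression
deformation or coefficient vector per frame), the standard output of 3D
morphable-model trackers. Everything downstream of the tracker — feature
construction, classification, comparison against human raters, and weight
interpretation — is implemented and testable here, on synthetic data.

# Pipeline

## Region-localized expression basis

A dense face mesh of `P` points is partitioned into four regions
(brows/forehead, eyes, nose/cheeks, mouth/chin) by assigning every point to
the facial feature of its nearest landmark among the 51 inner-face landmarks
(10 brow, 12 eye, 9 nose, 20 mouth). Distance ties go to the lowest landmark
index, making the partition deterministic; because only pairwise distances
enter, the partition is invariant under rigid motion of the mesh.

Trackers typically ship a *global* PCA expression basis `W` (3P × K) whose
components move the whole face and resist regional interpretation. The
localization procedure here — the published description states the goal
(60 localized components, region-countable, 7 of them nose/cheek) but not
the algorithm — is region masking followed by per-region orthonormalization:
rows of `W` outside a region are zeroed and the masked columns are
orthonormalized by QR, keeping the first `k_r` components per region. The
default split is 19 brows, 20 eyes, 7 nose/cheeks, 14 mouth (60 total).
The counts are configurable; 7 nose components is stated by the source
description, and 14 mouth components makes the mouth's share of channels
(14/56 = 25%) match the published mouth-feature baseline rate (~25.5%).
Components of different regions have disjoint support, so the full basis
`W'` has orthonormal columns, and the least-squares projection of a
deformation field reduces to an inner product, `e = W'ᵀ vec(ΔX)`.

The 7 nose/cheek coefficients are dropped after projection (they add little
expression information relative to the quadratic growth they would cause in
the feature count), leaving 53 expression channels.

## Behavior matrix

Head rotation is converted to intrinsic Z-Y-X Euler angles — yaw, then
pitch, then roll, in degrees, the common head-pose convention. The
composition/decomposition round-trips to 1e-6 away from gimbal lock; at
|pitch| = 90° the roll is set to 0, the residual freedom is folded into yaw,
and the result is flagged. The 53 expression channels and 3 pose channels
are stacked into the behavior matrix `Y` (56 × T); at the default 30 fps a
3-minute recording gives T = 5400.

## Windowed forward-lag cross-correlation features

Coordination between channels is summarized by windowed cross-correlation:
for a window length `Tw` (grid: 1, 2, 4, 6 s) the series is cut into
windows of `round(Tw·fps)` frames with 50% overlap (trailing partial window
discarded). Within a window, for the ordered pair (i, j), the Pearson
correlation between `i` and `j` *shifted forward by lag l* is maximized over
l = 0..L; only forward lags are allowed, so (i, j) measures i leading j and
is distinct from (j, i). The per-window maxima are summarized by their mean
`mu(i→j)` and population standard deviation `sigma(i→j)`. With 56 channels
and ordered pairs including the diagonal, the feature vector has
M = 2·56² = 6272 entries (the diagonal contributes constants — mu = 1,
sigma = 0 — which are harmless to a margin classifier and keep the printed
feature count exact).

Numerical choices, each made once:

* Correlation estimator: Pearson on the truncated overlapping segments, each
  segment re-centered and re-scaled (no zero padding, no detrending).
* Maximum lag: `floor(window/2)` frames by default (configurable), which
  keeps at least half a window of overlap at the largest lag.
* Signed maximum (not absolute value) over lags.
* Zero-variance segments contribute correlation 0 — a frozen face yields 0,
  not NaN. A relative variance guard (`var ≤ 1e-22 + 1e-13·mean-square`)
  distinguishes true degeneracy from cumulative-sum cancellation noise.
* `sigma` uses the two-pass population (ddof 0) formula, so constant maxima
  give exactly 0.
* Features are invariant under positive affine rescaling of any channel
  (Pearson invariance), so channel units never matter downstream.

The kernel (C++, one small BLAS product per window × lag) is verified against
an exhaustive per-window, per-lag brute-force oracle to 1e-10.

## Classification

A linear maximum-margin classifier at the default cost C = 1 predicts
ASD vs NT. No pre-installed R package provides a linear SVM, so the package
implements liblinear-style dual coordinate descent for the L2-regularized
hinge loss with the intercept as an augmented (regularized) constant
feature; on a fixture it reproduces scikit-learn's `LinearSVC(loss="hinge")`
coefficients to 8 decimals. Fits sweep samples in a fixed cyclic order, so
they are deterministic.

Cross-validation mirrors the study design: 10 outer folds over a seeded
shuffle of participant order, repeated (100 repeats in the study; tests use
fewer), with the window length `Tw` as the only tuned hyper-parameter,
selected by 5-fold inner CV on each outer training set (ties go to the
smaller `Tw`). Features are z-scored using training-fold statistics only —
the published pipeline does not say whether it standardized, but a margin
classifier on features of heterogeneous scale needs it, and the no-leakage
property is enforced by a canary test. Folds are plain (non-stratified) by
default, mirroring "shuffling participant order"; a stratified option
exists for heavily unbalanced cohorts. Leave-one-out CV is the same
machinery with n folds and no shuffle. Per-participant accuracy is the
fraction of repeated k-fold runs (5 folds × 1000 repeats in the study) in
which the participant is predicted correctly.

Accuracy, PPV, NPV, sensitivity and specificity come from the confusion
matrix with ASD as the positive class; an empty denominator yields `NA`
with a flag rather than a silent 0.

## Human-rater comparison

A rater panel is a raters × participants matrix of predicted labels with an
expertise stratum per rater. Group accuracy is the mean over raters of each
rater's fraction correct, overall and within strata (the overall value is
the rater-count-weighted stratum mean). Hard cases are participants whose
per-participant human accuracy is *strictly* below 50% (ties at the
threshold excluded), sorted ascending and joined with the model's
per-participant accuracy and leave-one-out prediction. Human–model
agreement is the Pearson correlation of the two per-participant accuracy
vectors, optionally after removing participants correctly classified by at
least 95% of raters; with 19 raters "at least 95%" is implemented as the
fraction compared with `>=` (19/19 = 100% qualifies, 18/19 ≈ 94.7% does
not). A constant vector after exclusion is an error, not a 0.

## Feature importance

Each feature name carries its two channels, each mapped to a category
(brow, eye, mouth, pose). Region-pair summaries report mean and sd of
|weight| per unordered category pair. Top-k category ratios are computed
under two conventions, because the published figure caption counts a
feature once per category it touches (*membership*) while the printed
baseline rates (~5.3% pose ≈ 3/56, ~25.5% mouth ≈ 14/56) are channel-
marginal (*slot*) counts: the slot convention counts each feature's two
sides separately (ratios sum to 1 at every k) and is the default because it
reproduces the printed baselines; membership ratios are reported on
request and may sum to more than 1. Ranking uses mean |weight| across CV
folds with ties broken by feature name.

# Synthetic data: what it emulates and what it does not

The study's videos and rater responses cannot be shared, so the package
generates cohorts that reproduce the *shape* of the data and a controllable
group effect:

* **Behavior channels** are AR(1) processes
  `x[t] = 0.6·x[t-1] + N(0, 1)` at 30 fps, T = 5400 (3 minutes), 56
  channels. AR(1) is the simplest process with realistic short-range
  autocorrelation; 0.6 gives a decorrelation time of a few frames,
  plausible for expression coefficients.
* **Group structure** is additive lagged linear coupling: for each planted
  ordered pair (i, j, lag), channel j receives `beta_g · x_i[t-lag]` inside
  its AR recursion, with `beta_g` depending on the participant's group.
  Defaults: 20 pairs at lag 3 frames (0.1 s, inside every window's lag
  range), beta 0.9 for ASD vs 0 for NT — a strong, recoverable effect used
  by the signal-recovery acceptance test. This is the simplest mechanism
  that makes the forward-lag `mu` features discriminative in the stated
  direction.
* **Rater panels** draw rater skill (expert mean 1.7, non-expert 1.2,
  sd 0.4) and participant difficulty (mean 0.5, sd 1.5) on the logit scale;
  a rater is correct with probability `plogis(skill + difficulty)`. These
  values were fixed a priori so that panel accuracy lands near the
  published ~0.78–0.83 band with a realistic spread of hard cases; they are
  not fitted to anything.
* **Meshes** are ellipsoidal point clouds with 51 landmarks laid out in
  anatomically ordered bands; the global expression basis is a random
  orthonormal matrix. Both are synthetic stand-ins: they exercise the
  geometry code but carry no anatomical deformation structure.

All randomness flows from one seed through per-participant substreams
(`seed + 7919·participant`), so cohorts are reproducible piecewise.

What a green test therefore establishes: the pipeline recovers planted
lag-coupling differences, is calibrated at chance when the groups are
exchangeable, and its bookkeeping (6272 features, 53 + 3 channels) matches
the published counts. What it does not establish: performance on real
facial dynamics, which are non-stationary, cross-correlated at rest, and
nonlinear — no claim about the published real-data accuracies is made or
checkable here.

# Known limitations and open choices

* The localization algorithm for the expression basis is this package's own
  reconstruction (masking + QR); the published model's exact construction
  and its per-region counts (other than nose = 7) are not machine-readable
  from the source. Counts are configurable where ours may differ.
* The published pipeline's maximum lag, correlation normalization, possible
  detrending, standardization, and inner-fold count are unstated; the
  choices above are documented defaults, not reverse-engineered facts.
* With unbalanced groups (15 vs 27), a margin classifier on null features
  has a mild majority-class bias, so chance-level accuracy sits slightly
  above 0.5; the null-calibration acceptance test inherits this and its
  binomial band should be read with that caveat.
* Dropped frames are not modeled; `interpolate_gaps()` exists but is never
  applied implicitly.
* Gimbal lock in the Euler decomposition is flagged, not avoided; head
  poses near |pitch| = 90° do not occur in seated conversation.
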