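---
title: "Methods: image-based weight-band estimation for dairy cattle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based weight-band estimation for dairy cattle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowbands)
```

## The problem

Routine weighing of dairy cattle is labour-intensive, so weights are
recorded less often than management decisions would like. A practical
alternative is to photograph each cow with a handheld device, segment her
silhouette, and predict a *weight band* — an ordinal category wide enough
to drive feeding and treatment decisions — from silhouette shape. Two
technical obstacles dominate: the apparent size of the animal depends on
the camera-to-animal distance, and repeated photographs of the same cow
are highly correlated, so naive evaluation overstates accuracy.

`cowbands` implements the full analysis chain for this setting:
silhouette morphometrics from binary masks, distance-based scale
normalisation, data-driven weight discretisation, a leak-safe grouped
classification pipeline, ordinal and calibration evaluation, and the
classical girth-tape baseline equations. Because no public image/weight
dataset exists for this task, the package ships a first-class synthetic
generator so that every stage is testable end to end.

## Synthetic herd and silhouettes

`sample_herd()` draws cow weights from a Gaussian mixture. The default is
nine equally likely components, 40 kg apart (420–740 kg), with a
within-band standard deviation of 6 kg. The component spacing reflects
weight bands that are wide enough to be actionable; the 6 kg within-band
spread keeps adjacent bands statistically distinguishable at herd sizes
of a few hundred animals, which is the regime in which a data-driven
banding of ~9 categories with at least 25 members per band is actually
identifiable. Heart girth is linked to weight by inverting the classical
mixed-breed girth-only equation (`BW = HG * 7.3827 - 878.3134`) plus
2 cm of Gaussian tape-measurement noise, so a 600 kg cow averages about
200 cm of girth. Body length and height follow an allometric power law
(linear dimension ∝ weight^(1/3)) anchored at a 1.70 m long, 1.45 m tall
600 kg reference cow.

`render_silhouette()` rasterises an analytic side-view shape — an
elliptical torso, four rectangular legs, an elliptical head, and a thin
hanging tail — under the pinhole relation: a length of `L` metres at
distance `d` spans `L * focal_px_m / d` pixels (`focal_px_m = 240` by
default, chosen so the working distance range fits a 384×288 canvas). A
pixel is foreground exactly when its centre lies inside the analytic
shape; this convention is unambiguous and lets tests check the projected
scale law (`area × d²` constant within rasterisation error) directly.
Pose jitter rotates the body axis and shifts the head. `perturb_mask()`
emulates the segmentation failure modes seen with real barn imagery:
whole thin appendages (found as the difference between the mask and its
morphological opening) vanish with probability equal to the severity, and
boundary pixels flicker, with foreground growth capped at a 1-pixel
dilation.

What the generator deliberately does **not** emulate: photographic
texture, occlusion by pen furniture or other animals, posture extremes
(grazing head-down, lying), perspective/tilt distortion, and
breed-specific conformation differences. Passing tests therefore show
that the *analysis chain* is correct and leak-free under controlled
shape–weight coupling — not that any particular accuracy level transfers
to real barn data.

## Morphometry

`extract_features()` measures the descriptors used for classification:
bounding-box width/height/area, mask area, convex-hull area, extent,
elongation, contour length, and seven classical invariant-moment
descriptors. All conventions are pinned so that independent brute-force
recomputation is possible:

* pixels are unit squares with centres at half-integer coordinates;
  bounding-box width is `max_col − min_col + 1`;
* the convex hull is taken over foreground pixel *corners*, so a solid
  rectangle's hull area equals its pixel count (taking centres instead
  would violate `mask_area ≤ hull_area`);
* elongation is `sqrt(λ₁/λ₂)` of the second central moment tensor with
  the per-pixel 1/12 unit-square correction, making an axis-aligned
  `W × H` rectangle score exactly `W/H`;
* contour length is the crack perimeter — the total length of
  foreground/background edges between unit pixels — because it is exact,
  translation-invariant, and trivially recomputable by enumeration;
* the seven invariant moments use plain pixel-centre normalised central
  moments (the field's standard choice for "moment-based descriptors",
  which are otherwise underspecified).

`clean_mask()` fills interior holes and removes connected components
below a pixel threshold (idempotent); when several components survive,
features are measured on the largest ("focal animal" semantics).

## Scale normalisation

Under the pinhole model one pixel spans
`mm_per_px_at_ref × d / ref_distance` millimetres for an object at
distance `d`. `normalize_features()` multiplies length features by this
factor and area features by its square, re-expressing everything at the
2.00 m reference distance — the stand-off at which handheld capture gives
the most consistent full-body framing. No camera intrinsics are assumed:
`mm_per_px_at_ref` defaults to 1 ("pixel-at-reference units"), because
classification needs *consistency* across distances, not absolute
millimetre accuracy. Normalisation uses the per-image *recorded* distance
(which carries simulated LiDAR jitter, 1 cm SD by default), mirroring
deployment, where the true distance is unknown.

## Data-driven weight bands

`fit_weight_bands()` fits a one-dimensional Gaussian mixture by EM for
each component count `K` in 3–10 and selects `K` by
`BIC = −2 logL + (3K − 1) log n`. EM details, which matter for
reproducibility, are fixed as: quantile-based initialisation plus five
random restarts, a variance floor of `1e-6 × var(x)`, and a relative
log-likelihood convergence tolerance of `1e-6`. Components whose interval
holds fewer than `min_count = 25` observations are merged — smallest
first, into the surviving component with the nearest mean, pooling means
and variances — until every band clears the floor. Small-cluster
occupancy is counted at the capture-event level (one observation per
weighing/photography event).

Ordered bands are converted to contiguous intervals whose cut points are
the posterior-equality crossovers between adjacent components. This
guarantees monotone labels (raw MAP assignment under unequal variances
can be non-monotone, which would break ordinal evaluation); a weight
exactly on a boundary takes the lower label. With all-identical input
the variance floor keeps EM defined and the fit collapses to one band.

A practical identifiability note, verified by simulation during design:
whether BIC resolves nine 40 kg-spaced components depends on both the
within-band spread and the sample size. At a within-band SD of 10 kg and
~270 animals, BIC genuinely prefers a coarser mixture — the
nine-component structure is then *not* recoverable by any correct
implementation. The defaults (SD 6 kg, herds of 360–405) sit inside the
recoverable regime, and the 25-member floor additionally requires about
40 expected members per band before multinomial fluctuation stops
randomly merging a band.

## Leak-safe classification

Per-image features are aggregated to one capture-level row by the
per-feature **median** (robust to a single corrupted mask in a burst of
five); the image count is retained. The girth covariate uses the measured
value when available and otherwise a constant 200 cm cohort prior with an
imputation indicator. The raw weight column never enters the feature
table.

`grouped_split()` assigns whole cows to a 20% holdout greedily,
minimising a divergence objective over holdout size and per-band counts,
so repeated observations of one cow can never straddle the boundary.
`run_cv()` uses five grouped folds (fold count is a free choice, made
configurable) balanced on each cow's modal band. Inside every training
fold only, the pipeline applies median imputation, robust scaling
(median/IQR), zero-variance removal, and SMOTE oversampling up to the
majority class (`k` neighbours capped at the smallest class count minus
one, so 25-member bands cannot break it); the classifier is an
extremely-randomised-trees ensemble — 500 trees, one random split
threshold per candidate feature, no bootstrap resampling, balanced class
weights, `√p` features per split. Macro-F1 is the primary metric.

Evaluation on the untouched holdout reports macro/weighted-F1, accuracy,
a percentile bootstrap CI (2000 event-level resamples; the resampling
unit and interval type are pinned choices), the ordinal decomposition
(adjacent = |Δband| = 1, non-adjacent ≥ 2, which partition the error rate
exactly), the multiclass Brier score (summed over classes, range 0–2),
and the expected calibration error over 10 equal-width top-confidence
bins with a reliability diagram via `autoplot()`. Pixelwise mask F1
(Dice) is provided as the segmentation-quality metric.

## Problem sizes and numerical checks

The test-suite simulations use herds of 360–405 cows (nine bands of
40–45), single capture events of 2–5 images, and 50-replicate seeded
sweeps for the banding-recovery property; these sizes were chosen as the
smallest at which the banding regime above is stable, keeping the whole
suite comfortably fast on one CPU. All metric implementations are checked
against one-line brute-force recomputations; the morphometric
descriptors are checked against independent pixel-enumeration, gift-
wrapping hull, and neighbour-count perimeter oracles on rasters ≤ 64×64;
the mixture fitter is cross-checked against an independent
model-based-clustering implementation on well-separated data.

## Known limitations

* The classifier treats bands as unordered classes; no explicitly
  ordinal objective is used (adjacent-error dominance is an emergent
  property, verified empirically).
* The calibration chain assumes a scalar per-image distance; depth-map
  aggregation, lens distortion, and tilt are out of scope.
* Synthetic silhouettes are side-view, single-animal, and texture-free;
  transfer of accuracy numbers to real imagery is explicitly not
  claimed.
* The manual baseline table is transcribed from its printed source,
  which contains typographic irregularities; one illegible MAPE cell is
  stored as `NA`, and age units are "as supplied" in the original
  campaign.
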