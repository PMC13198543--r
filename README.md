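# cowbands

Image-based **weight-band estimation for dairy cattle**: a leak-safe R
pipeline from single-animal silhouette masks to ordinal weight categories.

Routine weighing of dairy cows is labour-intensive, so weights are recorded
less often than feeding, health, and breeding decisions would like. A
practical alternative is to photograph each animal with a handheld device
that also records the camera-to-animal distance, segment the silhouette,
and classify the cow into a weight band. `cowbands` implements the complete
analysis for that setting:

* **Silhouette morphometrics** from binary masks: bounding box, mask and
  convex-hull area, extent, elongation, crack-perimeter contour length,
  and the seven classical invariant moment descriptors
  (`clean_mask()`, `extract_features()`).
* **Scale normalisation**: under the pinhole relation a pixel spans
  `mm_per_px_at_ref · d / d_ref` mm, so features are re-expressed at a
  common 2.00 m reference distance (`calibration()`,
  `normalize_features()`).
* **Data-driven weight bands**: a 1-D Gaussian mixture fitted by EM with
  `K` chosen by `BIC = −2 log L + (3K − 1) log n` over `K = 3…10`, then
  components holding fewer than 25 observations merged into their
  nearest-mean neighbour, yielding ordered bands with monotone interval
  assignment (`fit_weight_bands()`, `assign_bands()`).
* **Leak-safe classification**: burst-median aggregation, cow-level
  grouped 80:20 splitting and grouped 5-fold CV, fold-internal median
  imputation / robust scaling / SMOTE, and a 500-tree
  extremely-randomised-trees classifier with balanced class weights
  (`grouped_split()`, `run_cv()`, `fit_final()`).
* **Evaluation**: macro-F1 (primary) with a 2000-replicate percentile
  bootstrap CI, ordinal error decomposition (adjacent vs non-adjacent
  misclassifications partition the error rate), multiclass Brier score,
  expected calibration error with reliability bins, and pixelwise mask F1
  (`evaluate_holdout()`, `ordinal_decomposition()`, `mask_f1()`).
* **Manual baselines**: the classical girth-tape weight equations
  (mixed-breed, Swedish Red, Swedish Holstein) with MAPE/R² evaluation and
  OLS refitting (`manual_weight_equations()`, `predict_manual()`,
  `fit_ols_weight_equation()`).
* **Synthetic data**: a first-class generator for herds, analytic cow
  silhouettes rendered under the pinhole model, and segmentation-noise
  perturbation, so every stage is testable without barn data
  (`sample_herd()`, `render_silhouette()`, `perturb_mask()`,
  `generate_dataset()`).

Everything is tidyverse-shaped: feature tables are tibbles, fitted objects
have `tidy()`/`glance()` methods, and result objects have `autoplot()`
methods (band densities, reliability diagram).

## Worked example

```r
library(cowbands)

run <- run_weight_pipeline(n_cows = 45, images_per_event = 2,
                           weight_mixture = tibble::tibble(
                             mean_kg = c(480, 600, 720),
                             sd_kg = 6, prop = 1 / 3),
                           min_count = 5, n_folds = 0, n_boot = 200,
                           seed = 5)
run$band_model
#> <weight_band_model> K = 3 by BIC, 3 band(s) after merging 0 component(s)
#> band means (kg): 481, 599, 720
run$report
#> <eval_report> n = 9 holdout events
#>   macro-F1 1.000 (95% CI 1.000-1.000), weighted-F1 1.000, accuracy 1.000
#>   errors 0.0% (adjacent 0.0%, non-adjacent 0.0%); |distance| mean 0.000, median 0, max 0
#>   Brier 0.0040, ECE 0.0349
```

The driver simulates a 45-cow herd whose weights fall in three 120 kg-apart
groups, renders two silhouettes per cow at random stand-off distances with
segmentation noise, recovers the three weight bands from the recorded
weights, and classifies the 20% cow-level holdout perfectly — adjacent-band
errors would appear first as the bands move closer together. The Brier and
calibration numbers summarise how sharp and honest the predicted band
probabilities are.

At study scale (the defaults: 360 cows in nine 40 kg-apart bands, 5-image
bursts, noise severity 0.2) the holdout macro-F1 lands near 0.96 with all
errors in adjacent bands; permuting the band labels at cow level drops it
to chance (≈ 1/9), confirming the grouped pipeline cannot manufacture
signal.

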