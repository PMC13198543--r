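Package: cowbands
Title: Image-Based Weight-Band Estimation for Dairy Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A leak-safe pipeline for estimating ordinal body-weight bands of
    dairy cattle from single-animal silhouette masks captured with a handheld
    camera and a per-image stand-off distance. Provides silhouette
    morphometrics (bounding box, area, convex hull, elongation, contour
    length, invariant moments), pinhole-model scale normalisation to a common
    reference distance, data-driven weight discretisation via a
    one-dimensional Gaussian mixture with BIC selection and small-cluster
    merging, cow-level grouped train/holdout splitting and cross-validation,
    a median-imputation/robust-scaling/SMOTE/extremely-randomised-trees
    classification pipeline, ordinal error decomposition, bootstrap
    confidence intervals, probability-calibration diagnostics, classical
    girth-based manual weight equations, and a synthetic herd and silhouette
    generator so every stage is testable without barn data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    png,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
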