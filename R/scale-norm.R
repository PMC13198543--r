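#' Distance-to-scale calibration
#'
#' Under the pinhole relation, the physical span of one pixel grows linearly
#' with camera-to-animal distance. A calibration fixes the reference
#' distance and the millimetres-per-pixel factor at that reference; with
#' the default `mm_per_px_at_ref = 1` features are expressed in
#' "pixel-at-reference" units, which is sufficient for classification
#' (consistency matters, absolute millimetre accuracy does not).
#'
#' @param ref_distance_m Reference stand-off distance in metres. The default
#'   2.00 m is the distance at which handheld capture gives the most
#'   consistent full-body coverage.
#' @param mm_per_px_at_ref Millimetres spanned by one pixel for an object at
#'   the reference distance (device constant).
#' @return An object of class `"calibration"`.
#' @examples
#' calib <- calibration()
#' length_scale_factor(1.0, calib)
#' @export
calibration <- function(ref_distance_m = 2.0, mm_per_px_at_ref = 1.0) {
  check_positive_scalar(ref_distance_m, "ref_distance_m")
  check_positive_scalar(mm_per_px_at_ref, "mm_per_px_at_ref")
  structure(list(ref_distance_m = ref_distance_m,
                 mm_per_px_at_ref = mm_per_px_at_ref),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> ref %.2f m, %.4g mm/px at ref\n",
              x$ref_distance_m, x$mm_per_px_at_ref))
  invisible(x)
}

#' Pixels-to-millimetres factor at a capture distance
#'
#' Returns `mm_per_px_at_ref * distance_m / ref_distance_m`: an object twice
#' as far away appears half the size, so each of its pixels spans twice the
#' millimetres.
#'
#' @param distance_m Capture distance(s) in metres; vectorised.
#' @param calib A [calibration()] object.
#' @return Numeric vector of mm-per-pixel factors.
#' @export
length_scale_factor <- function(distance_m, calib = calibration()) {
  stopifnot(inherits(calib, "calibration"))
  if (!is.numeric(distance_m) || any(!is.finite(distance_m)) ||
      any(distance_m <= 0)) {
    abort("`distance_m` must be positive and finite.")
  }
  calib$mm_per_px_at_ref * distance_m / calib$ref_distance_m
}

#' Re-express pixel features at the common reference distance
#'
#' Length-based features are multiplied by the per-image pixels-to-mm
#' factor and area-based features by its square, so that features of the
#' same animal captured at different stand-off distances become comparable.
#' Dimensionless features (extent, elongation, moment descriptors) are
#' already distance-invariant and are passed through bit-identically.
#'
#' @param features A tibble of per-image features as returned by
#'   [extract_features()] (possibly many rows); extra non-feature columns
#'   (identifiers, metadata) are passed through unchanged.
#' @param distance_m Capture distance in metres, one value or one per row.
#'   Deployments use the recorded (possibly noisy) distance, not the true
#'   one.
#' @param calib A [calibration()] object.
#' @return A tibble with length columns renamed `*_mm`, area columns
#'   `*_mm2`, and dimensionless columns unchanged.
#' @examples
#' m <- matrix(0L, 16, 28); m[4:13, 5:24] <- 1L
#' extract_features(m) |> normalize_features(distance_m = 1.0)
#' @export
normalize_features <- function(features, distance_m, calib = calibration()) {
  stopifnot(is.data.frame(features))
  f <- length_scale_factor(distance_m, calib)
  if (!(length(f) == 1L || length(f) == nrow(features))) {
    abort("`distance_m` must have length 1 or nrow(features).")
  }
  out <- tibble::as_tibble(features)
  for (col in paste0(length_feature_cols(), "_px")) {
    if (col %in% names(out)) {
      new <- sub("_px$", "_mm", col)
      out[[new]] <- out[[col]] * f
      out[[col]] <- NULL
    }
  }
  for (col in paste0(area_feature_cols(), "_px2")) {
    if (col %in% names(out)) {
      new <- sub("_px2$", "_mm2", col)
      out[[new]] <- out[[col]] * f^2
      out[[col]] <- NULL
    }
  }
  out
}
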