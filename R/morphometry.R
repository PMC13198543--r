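#' Clean a silhouette mask
#'
#' Standard mask hygiene before morphometric measurement: interior holes are
#' filled, then 4-connected foreground components smaller than
#' `min_component_area_px` pixels are removed. The operation is idempotent.
#' If every component is removed the returned mask is empty; callers should
#' test with [mask_is_empty()] and typically skip such images.
#'
#' @param mask A 0/1 integer matrix (see [as_binary_mask()]).
#' @param min_component_area_px Minimum component area, in pixels, to keep.
#' @return A cleaned 0/1 integer matrix of the same dimensions.
#' @examples
#' m <- matrix(0L, 8, 8); m[2:6, 2:6] <- 1L; m[4, 4] <- 0L; m[8, 8] <- 1L
#' sum(clean_mask(m, min_component_area_px = 3))
#' @export
clean_mask <- function(mask, min_component_area_px = 64L) {
  mask <- as_binary_mask(mask)
  min_component_area_px <- check_count(min_component_area_px,
                                       "min_component_area_px", min = 0L)
  if (is_empty_mask(mask)) return(mask)
  filled <- as_binary_mask(EBImage::fillHull(mask))
  lab <- label_components(filled)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_component_area_px)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[lab %in% keep] <- 1L
  out
}

#' @rdname clean_mask
#' @export
mask_is_empty <- function(mask) is_empty_mask(as_binary_mask(mask))

# Restrict a mask to its largest 4-connected component ("focal animal").
largest_component <- function(mask) {
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  if (length(sizes) <= 1L) return(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[lab == which.max(sizes)] <- 1L
  out
}

# Crack-following perimeter: total length of the boundary between foreground
# and background along pixel edges (unit squares), i.e. for every foreground
# pixel the number of its 4-neighbours that are background or off-raster.
crack_perimeter <- function(mask) {
  p <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  p[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  core <- p[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
  nb <- p[1:nrow(mask), 2:(ncol(mask) + 1L)] +
    p[3:(nrow(mask) + 2L), 2:(ncol(mask) + 1L)] +
    p[2:(nrow(mask) + 1L), 1:ncol(mask)] +
    p[2:(nrow(mask) + 1L), 3:(ncol(mask) + 2L)]
  sum((4L - nb)[core == 1L])
}

# Convex-hull area over the corners of the foreground pixels' unit squares
# (0-based coordinates: pixel (row r, col c), 1-based in R, occupies
# [c-1, c] x [r-1, r]). Only boundary pixels contribute hull vertices.
hull_area_px <- function(mask) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("Mask is empty.")
  p <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  p[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  nb <- p[1:nrow(mask), 2:(ncol(mask) + 1L)] +
    p[3:(nrow(mask) + 2L), 2:(ncol(mask) + 1L)] +
    p[2:(nrow(mask) + 1L), 1:ncol(mask)] +
    p[2:(nrow(mask) + 1L), 3:(ncol(mask) + 2L)]
  boundary <- which(mask == 1L & nb < 4L, arr.ind = TRUE)
  if (nrow(boundary) == 0L) boundary <- idx
  x <- c(boundary[, "col"] - 1, boundary[, "col"],
         boundary[, "col"] - 1, boundary[, "col"])
  y <- c(boundary[, "row"] - 1, boundary[, "row"] - 1,
         boundary[, "row"], boundary[, "row"])
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  n <- length(h)
  abs(sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)) / 2
}

# Seven classical translation/scale/rotation-invariant moment combinations
# of the silhouette, from normalised central moments of pixel centres.
hu_moments <- function(mask) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  x <- idx[, "col"] - 0.5
  y <- idx[, "row"] - 0.5
  m00 <- length(x)
  xb <- mean(x); yb <- mean(y)
  mu <- function(p, q) sum((x - xb)^p * (y - yb)^q)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  c(
    n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2)
  )
}

#' Extract silhouette shape features from a binary mask
#'
#' Computes the morphometric descriptors used for weight classification:
#' tight bounding-box width/height/area, mask area, convex-hull area,
#' extent (mask area over bounding-box area), elongation, contour length,
#' and seven scale/rotation/translation-invariant moment descriptors.
#'
#' Conventions (pinned so independent recomputation is possible):
#' * Pixels are unit squares; pixel centres sit at half-integer 0-based
#'   coordinates. Bounding-box width is `max_col - min_col + 1`.
#' * The convex hull is taken over the corners of foreground pixels, so a
#'   solid rectangle has hull area equal to its pixel count.
#' * Elongation is `sqrt(lambda1 / lambda2)` of the second central moment
#'   tensor with the per-pixel 1/12 unit-square correction on the diagonal,
#'   so an axis-aligned W x H solid rectangle has elongation exactly W / H.
#' * Contour length is the crack perimeter: the total length of
#'   foreground/background edges between unit pixels (a W x H rectangle has
#'   contour length `2 * (W + H)`).
#'
#' If the mask holds several 4-connected components, features are measured
#' on the largest one (focal-animal semantics).
#'
#' @param mask A 0/1 integer matrix, normally output of [clean_mask()].
#' @return A one-row tibble with columns `bbox_width_px`, `bbox_height_px`,
#'   `bbox_area_px2`, `mask_area_px2`, `hull_area_px2`, `extent`,
#'   `elongation`, `contour_length_px`, `moment_hu1` ... `moment_hu7`.
#' @examples
#' m <- matrix(0L, 16, 28); m[4:13, 5:24] <- 1L
#' extract_features(m)
#' @export
extract_features <- function(mask) {
  mask <- as_binary_mask(mask)
  if (is_empty_mask(mask)) {
    abort("Mask is empty: no focal animal to measure.")
  }
  mask <- largest_component(mask)
  idx <- which(mask == 1L, arr.ind = TRUE)
  rows <- idx[, "row"]; cols <- idx[, "col"]
  w <- max(cols) - min(cols) + 1
  h <- max(rows) - min(rows) + 1
  area <- nrow(idx)
  x <- cols - 0.5; y <- rows - 0.5
  mu20 <- sum((x - mean(x))^2) / area + 1 / 12
  mu02 <- sum((y - mean(y))^2) / area + 1 / 12
  mu11 <- sum((x - mean(x)) * (y - mean(y))) / area
  tr2 <- (mu20 + mu02) / 2
  det_rt <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr2 + det_rt
  l2 <- max(tr2 - det_rt, .Machine$double.eps)
  hu <- hu_moments(mask)
  out <- tibble::tibble(
    bbox_width_px = w,
    bbox_height_px = h,
    bbox_area_px2 = w * h,
    mask_area_px2 = as.numeric(area),
    hull_area_px2 = hull_area_px(mask),
    extent = area / (w * h),
    elongation = sqrt(l1 / l2),
    contour_length_px = as.numeric(crack_perimeter(mask))
  )
  for (i in 1:7) out[[paste0("moment_hu", i)]] <- hu[i]
  out
}

# Column groups used by scale normalisation and the modelling pipeline.
length_feature_cols <- function() {
  c("bbox_width", "bbox_height", "contour_length")
}
area_feature_cols <- function() {
  c("bbox_area", "mask_area", "hull_area")
}
dimensionless_feature_cols <- function() {
  c("extent", "elongation", paste0("moment_hu", 1:7))
}
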