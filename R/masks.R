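#' Binary silhouette masks
#'
#' Throughout the package a silhouette mask is a plain integer matrix of 0s
#' and 1s: rows index image rows top-to-bottom, columns index image columns
#' left-to-right (row-major, origin top-left, 0-based pixel coordinates in
#' all documented conventions). Foreground connectivity is 4-connectivity.
#'
#' `as_binary_mask()` validates and coerces numeric/logical input (any value
#' > 0.5 becomes foreground, matching 8-bit PNG masks stored as 0/255).
#'
#' @param x A numeric or logical matrix.
#' @return An integer 0/1 matrix.
#' @examples
#' as_binary_mask(matrix(c(0, 255, 255, 0), 2, 2))
#' @export
as_binary_mask <- function(x) {
  if (!is.matrix(x)) abort("A binary mask must be a matrix.")
  if (is.logical(x)) {
    m <- matrix(as.integer(x), nrow(x), ncol(x))
  } else if (is.numeric(x)) {
    if (any(!is.finite(x))) abort("Mask contains non-finite values.")
    m <- matrix(as.integer(x > 0.5), nrow(x), ncol(x))
  } else {
    abort("A binary mask must be numeric or logical.")
  }
  m
}

is_empty_mask <- function(mask) sum(mask) == 0L

#' Read and write binary masks as PNG
#'
#' Masks are exchanged on disk as 8-bit single-channel PNG rasters with
#' background 0 and foreground 255.
#'
#' @param path File path.
#' @param mask A 0/1 integer matrix (see [as_binary_mask()]).
#' @return `read_mask_png()` returns a 0/1 integer matrix;
#'   `write_mask_png()` invisibly returns `path`.
#' @export
read_mask_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  as_binary_mask(arr)
}

#' @rdname read_mask_png
#' @export
write_mask_png <- function(mask, path) {
  mask <- as_binary_mask(mask)
  png::writePNG(matrix(as.double(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

# Label 4-connected foreground components; returns integer matrix of labels.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}
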