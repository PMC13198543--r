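# Internal helpers shared across modules.

# Deterministically derive a stage-specific sub-seed from one master seed so
# that independent stages (herd sampling, rendering, splitting, SMOTE, ...)
# do not consume from a single global RNG stream. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  chars <- utf8ToInt(as.character(stage))
  h <- (as.double(seed) %% 2147483647) + 1
  for (ch in chars) h <- (h * 31 + ch) %% 2147483563
  as.integer(h %% 2147483562) + 1L
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

#' Largest-remainder integer apportionment
#'
#' Splits `n` items into integer parts proportional to `props` using
#' largest-remainder (Hamilton) rounding, so the parts always sum to `n`.
#' Used for deterministic train/validation/test partition arithmetic.
#'
#' @param n Total number of items (non-negative integer).
#' @param props Numeric vector of non-negative proportions; normalised to
#'   sum to one.
#' @return Integer vector of the same length as `props`, summing to `n`.
#' @examples
#' largest_remainder_split(567, c(0.75, 0.15, 0.10))
#' @export
largest_remainder_split <- function(n, props) {
  n <- check_count(n, "n", min = 0L)
  if (!is.numeric(props) || any(!is.finite(props)) || any(props < 0) ||
      sum(props) <= 0) {
    abort("`props` must be non-negative with a positive sum.")
  }
  props <- props / sum(props)
  exact <- n * props
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- exact - base
    take <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}
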