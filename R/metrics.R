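# Classification, ordinal, and calibration metrics. All are written to be
# recomputable by one-line brute force, which the test suite does.

per_class_f1 <- function(y_true, y_pred, classes) {
  vapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
}

#' Classification summary metrics
#'
#' `macro_f1()` is the unweighted mean of per-class F1 scores over
#' `classes` (default: every label seen in truth or prediction; classes
#' with no true or predicted member score 0). `weighted_f1()` weights each
#' class F1 by its true-label support. `accuracy()` is the fraction of
#' exact matches.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Optional label set to average over.
#' @return A single number in `[0, 1]`.
#' @examples
#' macro_f1(c(0, 0, 1, 1), c(0, 1, 1, 1))
#' @export
macro_f1 <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred)) abort("Length mismatch.")
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  mean(per_class_f1(y_true, y_pred, classes))
}

#' @rdname macro_f1
#' @export
weighted_f1 <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred)) abort("Length mismatch.")
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  f1 <- per_class_f1(y_true, y_pred, classes)
  support <- vapply(classes, function(cl) sum(y_true == cl), numeric(1))
  sum(f1 * support) / sum(support)
}

#' @rdname macro_f1
#' @export
accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("Length mismatch.")
  mean(y_true == y_pred)
}

#' Ordinal error decomposition
#'
#' For integer-ordinal labels, decomposes the error rate into adjacent
#' (absolute class distance 1) and non-adjacent (distance >= 2)
#' misclassification rates — which partition the errors exactly — and
#' summarises the absolute class-distance distribution.
#'
#' @param y_true,y_pred Equal-length integer-ordinal label vectors.
#' @return A one-row tibble with `error_rate`, `adjacent_rate`,
#'   `nonadjacent_rate` (fractions of all samples), `dist_mean`,
#'   `dist_median`, `dist_max`.
#' @examples
#' ordinal_decomposition(0:4, c(0, 2, 2, 3, 1))
#' @export
ordinal_decomposition <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("Length mismatch.")
  if (length(y_true) == 0L) abort("Empty input.")
  d <- abs(as.integer(y_true) - as.integer(y_pred))
  adj <- mean(d == 1)
  nonadj <- mean(d >= 2)
  tibble::tibble(
    # summed so the partition identity holds to the last bit
    error_rate = adj + nonadj,
    adjacent_rate = adj,
    nonadjacent_rate = nonadj,
    dist_mean = mean(d),
    dist_median = median(d),
    dist_max = max(d)
  )
}

#' Percentile bootstrap confidence interval for a classification metric
#'
#' Resamples (truth, prediction) pairs with replacement `n_reps` times and
#' returns the `alpha/2` and `1 - alpha/2` empirical quantiles of the
#' metric. Resamples on which the metric is undefined (`NA`) are redrawn
#' and counted.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param metric Function `(y_true, y_pred) -> number`; default
#'   [macro_f1()].
#' @param n_reps Number of bootstrap replicates (default 2000).
#' @param alpha Two-sided miss probability (default 0.05 for a 95% CI).
#' @param seed Integer seed.
#' @return A list: `low`, `high`, `n_redrawn`, and the replicate vector
#'   `replicates`.
#' @export
bootstrap_ci <- function(y_true, y_pred, metric = macro_f1, n_reps = 2000L,
                         alpha = 0.05, seed = 1L) {
  n <- length(y_true)
  if (n < 2L || length(y_pred) != n) {
    abort("Need >= 2 equal-length observations.")
  }
  with_seed(derive_seed(seed, "bootstrap"), {
    reps <- numeric(n_reps)
    redrawn <- 0L
    for (b in seq_len(n_reps)) {
      val <- NA_real_
      tries <- 0L
      while (!is.finite(val) && tries < 1000L) {
        idx <- sample.int(n, n, replace = TRUE)
        val <- metric(y_true[idx], y_pred[idx])
        tries <- tries + 1L
        if (!is.finite(val)) redrawn <- redrawn + 1L
      }
      reps[b] <- val
    }
    qs <- quantile(reps, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                   na.rm = TRUE)
    list(low = qs[1], high = qs[2], n_redrawn = redrawn, replicates = reps)
  })
}

check_prob_rows <- function(prob, y_true) {
  if (!is.matrix(prob)) prob <- as.matrix(prob)
  if (nrow(prob) != length(y_true)) abort("Probability row count mismatch.")
  if (any(!is.finite(prob)) || any(prob < -1e-9)) {
    abort("Probabilities must be finite and non-negative.")
  }
  if (any(abs(rowSums(prob) - 1) > 1e-6)) {
    abort("Probability rows must sum to 1.")
  }
  if (is.null(colnames(prob))) colnames(prob) <- as.character(
    seq_len(ncol(prob)) - 1L)
  ix <- match(as.character(y_true), colnames(prob))
  if (any(is.na(ix))) abort("True labels not among probability columns.")
  list(prob = prob, true_ix = ix)
}

#' Multiclass Brier score
#'
#' Mean over samples of the squared Euclidean distance between the
#' predicted probability vector and the one-hot outcome, summed over
#' classes; ranges over `[0, 2]` (0 for confident correct, 2 for confident
#' wrong).
#'
#' @param prob Matrix of class probabilities, one row per sample; column
#'   names are class labels (defaults to `0, 1, ...`).
#' @param y_true True labels matching the columns.
#' @return The Brier score.
#' @examples
#' multiclass_brier(matrix(rep(1 / 9, 9), 1), 0)
#' @export
multiclass_brier <- function(prob, y_true) {
  pr <- check_prob_rows(prob, y_true)
  onehot <- matrix(0, nrow(pr$prob), ncol(pr$prob))
  onehot[cbind(seq_along(pr$true_ix), pr$true_ix)] <- 1
  mean(rowSums((pr$prob - onehot)^2))
}

#' Expected calibration error and reliability bins
#'
#' Bins the top-class confidence into `n_bins` equal-width bins on
#' `[0, 1]` and returns the count-weighted mean absolute gap between bin
#' accuracy and bin confidence, together with the per-bin table for
#' reliability plotting.
#'
#' @inheritParams multiclass_brier
#' @param n_bins Number of equal-width confidence bins (default 10).
#' @return A list: `ece` and `reliability_bins` (tibble with `bin`,
#'   `conf_lo`, `conf_hi`, `confidence`, `accuracy`, `count`).
#' @export
expected_calibration_error <- function(prob, y_true, n_bins = 10L) {
  pr <- check_prob_rows(prob, y_true)
  if (nrow(pr$prob) == 0L) abort("Empty input.")
  n_bins <- check_count(n_bins, "n_bins")
  conf <- apply(pr$prob, 1L, max)
  pred_ix <- apply(pr$prob, 1L, which.max)
  correct <- pred_ix == pr$true_ix
  bin <- pmin(pmax(ceiling(conf * n_bins), 1L), n_bins)
  tab <- tibble::tibble(bin = seq_len(n_bins),
                        conf_lo = (seq_len(n_bins) - 1) / n_bins,
                        conf_hi = seq_len(n_bins) / n_bins)
  agg <- tibble::tibble(bin = bin, conf = conf, correct = correct) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(confidence = mean(.data$conf),
                     accuracy = mean(.data$correct),
                     count = dplyr::n(), .groups = "drop")
  tab <- dplyr::left_join(tab, agg, by = "bin") |>
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0L))
  n <- nrow(pr$prob)
  ece <- sum(tab$count / n * abs(tab$accuracy - tab$confidence),
             na.rm = TRUE)
  list(ece = ece, reliability_bins = tab)
}

#' Pixelwise mask F1 (Dice) score
#'
#' `2 |P intersect T| / (|P| + |T|)` between a predicted and a reference
#' silhouette of identical raster dimensions: 1 for identical masks, 0 for
#' disjoint ones. Two empty masks score 1 by convention.
#'
#' @param pred,truth 0/1 integer matrices of equal dimensions.
#' @return F1 in `[0, 1]`.
#' @examples
#' a <- matrix(0L, 4, 4); a[2:3, 2:3] <- 1L
#' mask_f1(a, a)
#' @export
mask_f1 <- function(pred, truth) {
  pred <- as_binary_mask(pred); truth <- as_binary_mask(truth)
  if (!all(dim(pred) == dim(truth))) {
    abort("Masks must have identical dimensions.")
  }
  denom <- sum(pred) + sum(truth)
  if (denom == 0L) return(1)
  2 * sum(pred * truth) / denom
}
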