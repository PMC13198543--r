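# Leak-safe classification harness: burst aggregation, cow-level grouped
# splitting, fold-internal preprocessing + SMOTE, an extremely-randomised
# trees classifier, grouped cross-validation, and holdout evaluation.

id_cols <- function() c("cow_id", "event_id")

feature_cols_of <- function(table) {
  drop <- c(id_cols(), "band", "true_weight_kg", "distance_m",
            "true_distance_m", "image_index", "fold")
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  setdiff(num, drop)
}

#' Aggregate a burst of per-image features to one capture-level row
#'
#' Multiple images of the same capture event are segmented and measured
#' individually; their feature rows are collapsed to a single observation
#' by the per-feature median, which is robust to a single corrupted mask in
#' the burst. The number of contributing images is retained as `n_images`.
#'
#' @param features A tibble of per-image feature rows. If `cow_id` /
#'   `event_id` columns are present, aggregation is per event; otherwise
#'   all rows are treated as one burst.
#' @return A tibble with one row per event.
#' @export
aggregate_burst <- function(features) {
  stopifnot(is.data.frame(features))
  if (nrow(features) == 0L) abort("No feature rows to aggregate.")
  num <- names(features)[vapply(features, is.numeric, logical(1))]
  num <- setdiff(num, "image_index")
  if (all(id_cols() %in% names(features))) {
    features |>
      dplyr::group_by(dplyr::across(dplyr::all_of(id_cols()))) |>
      dplyr::summarise(
        dplyr::across(dplyr::all_of(num), median),
        n_images = dplyr::n(), .groups = "drop")
  } else {
    out <- features |>
      dplyr::summarise(dplyr::across(dplyr::all_of(num), median))
    out$n_images <- nrow(features)
    out
  }
}

#' Build the capture-level feature table from a synthetic dataset
#'
#' Runs the full measurement chain on a [generate_dataset()] result: mask
#' cleaning, morphometric extraction, scale normalisation using each
#' event's *recorded* distance, burst aggregation, and attachment of the
#' girth covariate. When a measured girth is absent the cohort prior
#' `girth_prior_cm` (default 200 cm) is substituted and flagged in
#' `girth_imputed`. The raw weight never enters the table; the ordinal
#' target is attached separately via [assign_bands()].
#'
#' @param dataset A `"capture_dataset"`.
#' @param calib A [calibration()].
#' @param min_component_area_px Cleaning threshold, see [clean_mask()].
#' @param girth_measured Logical: attach the dataset's per-cow girth
#'   (`TRUE`, default) or fall back to the constant prior.
#' @param girth_prior_cm Constant girth prior (cm).
#' @return A tibble with one row per event: identifiers, normalised
#'   features, `n_images`, `heart_girth_cm`, `girth_imputed`.
#' @export
build_feature_table <- function(dataset, calib = calibration(),
                                min_component_area_px = 64L,
                                girth_measured = TRUE,
                                girth_prior_cm = 200) {
  stopifnot(inherits(dataset, "capture_dataset"))
  caps <- dataset$captures
  rows <- vector("list", nrow(caps))
  for (i in seq_len(nrow(caps))) {
    m <- clean_mask(caps$mask[[i]], min_component_area_px)
    if (mask_is_empty(m)) next
    rows[[i]] <- extract_features(m) |>
      normalize_features(caps$distance_m[i], calib) |>
      dplyr::mutate(cow_id = caps$cow_id[i], event_id = caps$event_id[i],
                    .before = 1)
  }
  per_image <- dplyr::bind_rows(rows)
  if (nrow(per_image) == 0L) abort("Every mask was empty after cleaning.")
  ft <- aggregate_burst(per_image)
  if (girth_measured) {
    girth <- dataset$ground_truth |>
      dplyr::select("event_id", "heart_girth_cm")
    ft <- dplyr::left_join(ft, girth, by = "event_id") |>
      dplyr::mutate(
        girth_imputed = as.integer(is.na(.data$heart_girth_cm)),
        heart_girth_cm = dplyr::coalesce(.data$heart_girth_cm,
                                         girth_prior_cm))
  } else {
    ft$heart_girth_cm <- girth_prior_cm
    ft$girth_imputed <- 1L
  }
  ft
}

#' Cow-level grouped train/holdout split
#'
#' Assigns whole cows to the holdout so that no cow contributes events to
#' both partitions. Cows are added greedily (in seeded random order for
#' tie-breaking) choosing at each step the cow whose addition most reduces
#' a divergence objective combining the holdout-size gap and the gap
#' between per-band holdout counts and `holdout_frac` of each band's total;
#' the greedy stops when no addition improves it. When band sizes divide
#' evenly this lands exactly on the target fraction.
#'
#' @param table A feature table with `cow_id`, `event_id` and the ordinal
#'   target column `band`.
#' @param holdout_frac Target holdout fraction of events (default 0.20).
#' @param seed Integer seed for tie-breaking.
#' @return An object of class `"grouped_split"`: `train_event_ids`,
#'   `holdout_event_ids`, `group_map` (tibble `event_id`, `cow_id`),
#'   `holdout_frac_achieved`.
#' @export
grouped_split <- function(table, holdout_frac = 0.2, seed = 1L) {
  stopifnot(is.data.frame(table))
  need <- c(id_cols(), "band")
  if (!all(need %in% names(table))) {
    abort("`table` needs columns cow_id, event_id, band.")
  }
  cows <- unique(table$cow_id)
  if (length(cows) < 2L) abort("Need at least two cows to split.")
  if (holdout_frac <= 0 || holdout_frac >= 1) {
    abort("`holdout_frac` must be in (0, 1).")
  }
  classes <- sort(unique(table$band))
  cnt <- function(sub) {
    vapply(classes, function(cl) sum(sub$band == cl), numeric(1))
  }
  total <- cnt(table)
  n_total <- nrow(table)
  per_cow <- lapply(setNames(cows, cows),
                    function(cid) cnt(table[table$cow_id == cid, ]))
  objective <- function(hold_cnt) {
    n_hold <- sum(hold_cnt)
    (n_hold - holdout_frac * n_total)^2 / n_total^2 +
      sum((hold_cnt - holdout_frac * total)^2) / n_total^2
  }
  order_cows <- with_seed(derive_seed(seed, "split"), sample(cows))
  hold <- character(0)
  hold_cnt <- numeric(length(classes))
  j_cur <- objective(hold_cnt)
  remaining <- order_cows
  repeat {
    if (length(remaining) <= 1L) break  # keep >= 1 cow in training
    js <- vapply(remaining,
                 function(cid) objective(hold_cnt + per_cow[[cid]]),
                 numeric(1))
    best <- which.min(js)
    if (js[best] >= j_cur - 1e-12) break
    cid <- remaining[best]
    hold <- c(hold, cid)
    hold_cnt <- hold_cnt + per_cow[[cid]]
    j_cur <- js[best]
    remaining <- setdiff(remaining, cid)
  }
  if (length(hold) == 0L) hold <- remaining[1L]
  in_hold <- table$cow_id %in% hold
  structure(list(
    train_event_ids = table$event_id[!in_hold],
    holdout_event_ids = table$event_id[in_hold],
    group_map = tibble::tibble(event_id = table$event_id,
                               cow_id = table$cow_id),
    holdout_frac_achieved = mean(in_hold)
  ), class = "grouped_split")
}

#' @export
print.grouped_split <- function(x, ...) {
  cat(sprintf("<grouped_split> %d train / %d holdout events (%.1f%% holdout)\n",
              length(x$train_event_ids), length(x$holdout_event_ids),
              100 * x$holdout_frac_achieved))
  invisible(x)
}

#' Classification pipeline specification
#'
#' Bundles the preprocessing and classifier settings: median imputation,
#' robust scaling (median/IQR), removal of zero-variance features,
#' fold-internal SMOTE oversampling, and an extremely-randomised-trees
#' classifier (500 trees, balanced class weights). All fitting of these
#' steps happens inside training folds only.
#'
#' @param smote Apply SMOTE inside training data (default `TRUE`).
#' @param smote_k_neighbors Neighbour count for SMOTE; per fold it is
#'   capped at the smallest class count minus one.
#' @param n_trees Number of trees (default 500).
#' @param class_weight `"balanced"` (inverse-frequency) or `"none"`.
#' @param drop_zero_variance Remove zero-variance features (default
#'   `TRUE`).
#' @param mtry_frac Fraction of features tried per split; `NULL` uses the
#'   square-root default.
#' @param min_node_size Minimum node size (default 1).
#' @return An object of class `"pipeline_spec"`.
#' @export
pipeline_spec <- function(smote = TRUE, smote_k_neighbors = 5L,
                          n_trees = 500L, class_weight = "balanced",
                          drop_zero_variance = TRUE, mtry_frac = NULL,
                          min_node_size = 1L) {
  structure(list(smote = smote, smote_k_neighbors = smote_k_neighbors,
                 n_trees = n_trees, class_weight = class_weight,
                 drop_zero_variance = drop_zero_variance,
                 mtry_frac = mtry_frac, min_node_size = min_node_size),
            class = "pipeline_spec")
}

fit_preprocessor <- function(X, drop_zero_variance = TRUE) {
  med <- vapply(X, function(col) median(col, na.rm = TRUE), numeric(1))
  med[!is.finite(med)] <- 0
  iqr <- vapply(X, function(col) {
    q <- quantile(col, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    q[2] - q[1]
  }, numeric(1))
  iqr[!is.finite(iqr) | iqr <= 0] <- 1
  keep <- names(X)
  if (drop_zero_variance) {
    v <- vapply(X, function(col) var(col, na.rm = TRUE), numeric(1))
    keep <- names(X)[is.finite(v) & v > 0]
    if (length(keep) == 0L) abort("All features have zero variance.")
  }
  list(median = med, iqr = iqr, keep = keep)
}

apply_preprocessor <- function(prep, X) {
  X <- X[, prep$keep, drop = FALSE]
  for (col in names(X)) {
    v <- X[[col]]
    v[is.na(v)] <- prep$median[[col]]
    X[[col]] <- (v - prep$median[[col]]) / prep$iqr[[col]]
  }
  X
}

# SMOTE: oversample every minority class up to the majority count by
# interpolating between a class member and one of its k nearest same-class
# neighbours (uniform interpolation weight). Singleton classes are
# duplicated. Returns the augmented matrix, labels, and a synthetic flag.
smote_oversample <- function(X, y, k_neighbors = 5L, seed = 1L) {
  X <- as.matrix(X)
  counts <- table(y)
  n_max <- max(counts)
  with_seed(derive_seed(seed, "smote"), {
    add_X <- list(); add_y <- list()
    for (cl in names(counts)) {
      need <- n_max - counts[[cl]]
      if (need == 0) next
      idx <- which(y == cl)
      Xc <- X[idx, , drop = FALSE]
      nc <- nrow(Xc)
      if (nc == 1L) {
        add_X[[cl]] <- Xc[rep(1L, need), , drop = FALSE]
        add_y[[cl]] <- rep(cl, need)
        next
      }
      k <- min(k_neighbors, nc - 1L)
      d <- as.matrix(stats::dist(Xc))
      diag(d) <- Inf
      nn <- apply(d, 1L, function(r) order(r)[seq_len(k)])
      nn <- matrix(nn, nrow = k)
      base <- sample.int(nc, need, replace = TRUE)
      pick <- nn[cbind(sample.int(k, need, replace = TRUE), base)]
      u <- runif(need)
      add_X[[cl]] <- Xc[base, , drop = FALSE] +
        u * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
      add_y[[cl]] <- rep(cl, need)
    }
    if (length(add_X) == 0L) {
      list(X = X, y = y, synthetic = rep(FALSE, length(y)))
    } else {
      Xa <- do.call(rbind, add_X)
      list(X = rbind(X, Xa),
           y = c(y, unlist(add_y, use.names = FALSE)),
           synthetic = c(rep(FALSE, length(y)), rep(TRUE, nrow(Xa))))
    }
  })
}

#' Fit the weight-band classifier on a training table
#'
#' Fits the full leak-safe pipeline on the given (training) rows:
#' preprocessing (median imputation, robust scaling, zero-variance
#' removal) and SMOTE are fitted on these rows only, then an
#' extremely-randomised-trees probability forest is grown. The returned
#' model records the training event ids and the per-class SMOTE bookkeeping
#' so leakage can be audited.
#'
#' @param table Training feature table with `cow_id`, `event_id`, feature
#'   columns and the target `band`.
#' @param spec A [pipeline_spec()].
#' @param seed Integer seed (threads the SMOTE draws and the forest).
#' @return An object of class `"weight_classifier"`.
#' @export
fit_final <- function(table, spec = pipeline_spec(), seed = 1L) {
  stopifnot(inherits(spec, "pipeline_spec"), is.data.frame(table))
  if (!"band" %in% names(table)) abort("`table` must contain target `band`.")
  feats <- feature_cols_of(table)
  if (length(feats) == 0L) abort("No feature columns found.")
  y <- as.character(table$band)
  if (length(unique(y)) < 2L) abort("Need at least two classes to fit.")
  prep <- fit_preprocessor(table[, feats, drop = FALSE],
                           spec$drop_zero_variance)
  X <- apply_preprocessor(prep, table[, feats, drop = FALSE])
  smote_info <- NULL
  synthetic <- rep(FALSE, nrow(X))
  if (isTRUE(spec$smote)) {
    k <- min(spec$smote_k_neighbors, min(table(y)) - 1L)
    sm <- smote_oversample(X, y, k_neighbors = max(k, 1L), seed = seed)
    smote_info <- tibble::tibble(
      class = names(table(y)),
      n_original = as.integer(table(y)),
      n_synthetic = as.integer(table(factor(sm$y[sm$synthetic],
                                            levels = names(table(y))))))
    X <- as.data.frame(sm$X)
    y <- sm$y
    synthetic <- sm$synthetic
  }
  classes <- sort(unique(y))
  cw <- if (identical(spec$class_weight, "balanced")) {
    tab <- table(factor(y, levels = classes))
    as.numeric(length(y) / (length(classes) * tab))
  } else {
    rep(1, length(classes))
  }
  mtry <- if (is.null(spec$mtry_frac)) {
    max(1L, floor(sqrt(ncol(X))))
  } else {
    max(1L, floor(spec$mtry_frac * ncol(X)))
  }
  df <- X
  df$.band <- factor(y, levels = classes)
  forest <- ranger::ranger(
    dependent.variable.name = ".band", data = df,
    num.trees = spec$n_trees, mtry = mtry,
    min.node.size = spec$min_node_size,
    splitrule = "extratrees", num.random.splits = 1L,
    replace = FALSE, sample.fraction = 1,
    probability = TRUE, class.weights = cw,
    seed = derive_seed(seed, "forest"), num.threads = 1L)
  structure(list(
    spec = spec, preprocessor = prep, forest = forest,
    feature_cols = feats, classes = classes,
    train_event_ids = table$event_id,
    train_cow_ids = unique(table$cow_id),
    smote_info = smote_info,
    n_train = nrow(table), n_synthetic = sum(synthetic)
  ), class = "weight_classifier")
}

#' @export
print.weight_classifier <- function(x, ...) {
  cat(sprintf(
    "<weight_classifier> extra-trees (%d trees), %d classes, %d training events (+%d SMOTE rows)\n",
    x$spec$n_trees, length(x$classes), x$n_train, x$n_synthetic))
  invisible(x)
}

#' Predict weight bands or class probabilities
#'
#' @param object A [fit_final()] model.
#' @param newdata Feature table rows.
#' @param type `"class"` for integer band labels, `"prob"` for a matrix of
#'   class probabilities (rows sum to 1, columns named by band label).
#' @param ... Unused.
#' @return Integer labels or a probability matrix.
#' @export
predict.weight_classifier <- function(object, newdata,
                                      type = c("class", "prob"), ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$feature_cols, names(newdata))
  if (length(missing_cols) > 0L) {
    abort(paste0("Feature columns missing from newdata: ",
                 paste(missing_cols, collapse = ", ")))
  }
  X <- apply_preprocessor(object$preprocessor,
                          newdata[, object$feature_cols, drop = FALSE])
  pr <- predict(object$forest, data = X, num.threads = 1L)$predictions
  colnames(pr) <- object$forest$forest$levels
  pr <- pr[, order(as.numeric(colnames(pr))), drop = FALSE]
  if (type == "prob") return(pr)
  as.integer(colnames(pr)[apply(pr, 1L, which.max)])
}

#' @describeIn fit_final Per-class SMOTE bookkeeping and class weights.
#' @param x A `"weight_classifier"`.
#' @param ... Unused.
#' @export
tidy.weight_classifier <- function(x, ...) {
  if (is.null(x$smote_info)) {
    tibble::tibble(class = x$classes, n_original = NA_integer_,
                   n_synthetic = 0L)
  } else {
    x$smote_info
  }
}

#' @describeIn fit_final One-row fit summary.
#' @export
glance.weight_classifier <- function(x, ...) {
  tibble::tibble(n_train = x$n_train, n_synthetic = x$n_synthetic,
                 n_classes = length(x$classes),
                 n_features = length(x$preprocessor$keep),
                 n_trees = x$spec$n_trees)
}

make_grouped_folds <- function(table, n_folds, seed) {
  cow_band <- table |>
    dplyr::group_by(.data$cow_id) |>
    dplyr::summarise(modal_band = names(which.max(table(.data$band))),
                     .groups = "drop")
  with_seed(derive_seed(seed, "folds"), {
    cow_band <- cow_band[sample.int(nrow(cow_band)), ]
    cow_band <- cow_band[order(cow_band$modal_band), ]
    cow_band$fold <- rep_len(seq_len(n_folds), nrow(cow_band))
    cow_band
  })
}

#' Grouped cross-validation of the pipeline
#'
#' Splits cows (never events) into `n_folds` folds balanced on each cow's
#' modal band, then for each fold fits the full pipeline — preprocessing
#' and SMOTE included — on the other folds only and scores the held-out
#' fold. Macro-F1 is the primary metric; weighted-F1 and accuracy are
#' secondary.
#'
#' @param table Feature table with target `band`.
#' @param spec A [pipeline_spec()].
#' @param n_folds Number of grouped folds (default 5).
#' @param seed Integer seed.
#' @return A tibble with one row per fold (`fold`, `n_train`, `n_val`,
#'   `macro_f1`, `weighted_f1`, `accuracy`); the mean metrics are attached
#'   as attribute `"summary"` and fold membership as attribute `"folds"`.
#' @export
run_cv <- function(table, spec = pipeline_spec(), n_folds = 5L, seed = 1L) {
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  if (length(unique(table$cow_id)) < n_folds) {
    abort("Fewer cows than folds.")
  }
  folds <- make_grouped_folds(table, n_folds, seed)
  table <- dplyr::left_join(table, folds[, c("cow_id", "fold")],
                            by = "cow_id")
  classes <- sort(unique(table$band))
  out <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    train <- table[table$fold != f, names(table) != "fold"]
    val <- table[table$fold == f, names(table) != "fold"]
    if (nrow(val) == 0L) abort("Empty validation fold.")
    if (length(setdiff(classes, unique(train$band))) > 0L) {
      abort(sprintf("Class absent from the training side of fold %d.", f))
    }
    model <- fit_final(train, spec, seed = derive_seed(seed, paste0("cv", f)))
    pred <- predict(model, val)
    out[[f]] <- tibble::tibble(
      fold = f, n_train = nrow(train), n_val = nrow(val),
      macro_f1 = macro_f1(val$band, pred, classes = classes),
      weighted_f1 = weighted_f1(val$band, pred, classes = classes),
      accuracy = accuracy(val$band, pred))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "summary") <- res |>
    dplyr::summarise(dplyr::across(c("macro_f1", "weighted_f1", "accuracy"),
                                   mean))
  attr(res, "folds") <- folds
  res
}

#' Evaluate a fitted classifier on the grouped holdout
#'
#' Computes the full evaluation report on untouched holdout rows: macro-F1
#' (primary) with a percentile-bootstrap confidence interval, weighted-F1,
#' accuracy, the ordinal error decomposition, multiclass Brier score,
#' expected calibration error with reliability bins, and the confusion
#' matrix.
#'
#' @param model A [fit_final()] model.
#' @param holdout Holdout feature table with target `band`.
#' @param n_boot Bootstrap replicates for the macro-F1 CI (default 2000).
#' @param alpha Two-sided CI miss probability (default 0.05).
#' @param n_bins Calibration bins (default 10).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `"eval_report"`.
#' @export
evaluate_holdout <- function(model, holdout, n_boot = 2000L, alpha = 0.05,
                             n_bins = 10L, seed = 1L) {
  stopifnot(inherits(model, "weight_classifier"))
  overlap <- intersect(model$train_event_ids, holdout$event_id)
  if (length(overlap) > 0L) {
    abort("Holdout rows overlap the training events; evaluation would leak.")
  }
  y <- as.integer(holdout$band)
  pred <- predict(model, holdout, type = "class")
  prob <- predict(model, holdout, type = "prob")
  classes <- sort(unique(c(y, as.integer(colnames(prob)))))
  ci <- bootstrap_ci(y, pred, metric = macro_f1, n_reps = n_boot,
                     alpha = alpha, seed = seed)
  cal <- expected_calibration_error(prob, y, n_bins = n_bins)
  conf <- table(factor(y, levels = classes),
                factor(pred, levels = classes))
  structure(list(
    macro_f1 = macro_f1(y, pred, classes = classes),
    weighted_f1 = weighted_f1(y, pred, classes = classes),
    accuracy = accuracy(y, pred),
    ci_low = ci$low, ci_high = ci$high, n_boot = n_boot,
    ordinal = ordinal_decomposition(y, pred),
    brier = multiclass_brier(prob, y),
    ece = cal$ece,
    reliability_bins = cal$reliability_bins,
    confusion = conf,
    n_holdout = length(y),
    y_true = y, y_pred = pred, prob = prob
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d holdout events\n", x$n_holdout))
  cat(sprintf("  macro-F1 %.3f (95%% CI %.3f-%.3f), weighted-F1 %.3f, accuracy %.3f\n",
              x$macro_f1, x$ci_low, x$ci_high, x$weighted_f1, x$accuracy))
  o <- x$ordinal
  cat(sprintf("  errors %.1f%% (adjacent %.1f%%, non-adjacent %.1f%%); |distance| mean %.3f, median %g, max %g\n",
              100 * o$error_rate, 100 * o$adjacent_rate,
              100 * o$nonadjacent_rate, o$dist_mean, o$dist_median,
              o$dist_max))
  cat(sprintf("  Brier %.4f, ECE %.4f\n", x$brier, x$ece))
  invisible(x)
}

#' @describeIn evaluate_holdout Reliability-bin table (one row per bin).
#' @param x An `"eval_report"`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) x$reliability_bins

#' @describeIn evaluate_holdout One-row metric summary.
#' @export
glance.eval_report <- function(x, ...) {
  o <- x$ordinal
  tibble::tibble(
    n = x$n_holdout, macro_f1 = x$macro_f1, ci_low = x$ci_low,
    ci_high = x$ci_high, weighted_f1 = x$weighted_f1,
    accuracy = x$accuracy, error_rate = o$error_rate,
    adjacent_rate = o$adjacent_rate, nonadjacent_rate = o$nonadjacent_rate,
    dist_mean = o$dist_mean, dist_median = o$dist_median,
    dist_max = o$dist_max, brier = x$brier, ece = x$ece)
}

#' @describeIn evaluate_holdout Reliability diagram (bin confidence vs
#'   accuracy, point size by bin count).
#' @param object An `"eval_report"`.
#' @export
autoplot.eval_report <- function(object, ...) {
  bins <- object$reliability_bins |> dplyr::filter(.data$count > 0)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$confidence,
                                     y = .data$accuracy)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "top-class confidence", y = "empirical accuracy",
                  size = "events",
                  title = sprintf("Reliability diagram (ECE = %.3f)",
                                  object$ece))
}
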