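#' Run the full weight-band estimation study on synthetic data
#'
#' End-to-end driver wiring every stage together: herd and capture
#' simulation, mask cleaning, morphometric extraction, scale normalisation
#' to the 2.00 m reference, burst aggregation, data-driven weight banding
#' (GMM + BIC + merging), cow-level grouped 80:20 splitting, grouped
#' cross-validation, final refit on the training partition, and one-shot
#' evaluation on the untouched holdout.
#'
#' The defaults encode the study conditions the synthetic herd emulates: a
#' nine-component weight mixture with enough members per band, five-image
#' bursts, stand-off distances 1.44-2.72 m, moderate segmentation noise
#' (severity 0.2), and a 20% grouped holdout.
#'
#' @param n_cows Herd size (default 360: nine bands of ~40 cows, enough
#'   that every band clears the 25-member occupancy floor with high
#'   probability under multinomial sampling).
#' @param events_per_cow,images_per_event Capture structure (defaults 1
#'   and 5).
#' @param severity,pose_jitter,distance_noise_sd Noise levels, see
#'   [generate_dataset()].
#' @param weight_mixture Herd weight mixture, see [sample_herd()].
#' @param min_count Minimum band occupancy for [fit_weight_bands()].
#' @param holdout_frac Grouped holdout fraction (default 0.20).
#' @param spec A [pipeline_spec()].
#' @param n_folds Grouped CV folds (default 5); `0` skips CV.
#' @param n_boot Bootstrap replicates for the holdout CI.
#' @param permute_labels If `TRUE`, permutes band labels at cow level
#'   before modelling — a chance-level null run used to verify that the
#'   leak-safe harness cannot manufacture signal.
#' @param seed Master seed; all stages derive sub-seeds from it.
#' @return A list with class `"weight_pipeline_run"`: `feature_table`,
#'   `band_model`, `split`, `cv` (or `NULL`), `model`, `report`, `herd`.
#' @examples
#' \donttest{
#' run <- run_weight_pipeline(n_cows = 45, images_per_event = 2,
#'                            n_boot = 200, n_folds = 0, seed = 1)
#' glance(run$report)
#' }
#' @export
run_weight_pipeline <- function(n_cows = 360L, events_per_cow = 1L,
                                images_per_event = 5L,
                                severity = 0.2, pose_jitter = 0.05,
                                distance_noise_sd = 0.01,
                                weight_mixture = default_weight_mixture(),
                                min_count = 25L,
                                holdout_frac = 0.2,
                                spec = pipeline_spec(),
                                n_folds = 5L, n_boot = 2000L,
                                permute_labels = FALSE,
                                seed = 1L) {
  dataset <- generate_dataset(
    n_cows = n_cows, events_per_cow = events_per_cow,
    images_per_event = images_per_event, severity = severity,
    pose_jitter = pose_jitter, distance_noise_sd = distance_noise_sd,
    weight_mixture = weight_mixture, seed = seed)
  ft <- build_feature_table(dataset)

  band_model <- fit_weight_bands(dataset$ground_truth$true_weight_kg,
                                 min_count = min_count, seed = seed)
  bands <- tibble::tibble(
    event_id = dataset$ground_truth$event_id,
    band = assign_bands(dataset$ground_truth$true_weight_kg, band_model))
  ft <- dplyr::left_join(ft, bands, by = "event_id")

  if (isTRUE(permute_labels)) {
    # permute at cow level so the grouping structure stays intact
    cow_band <- ft |>
      dplyr::distinct(.data$cow_id, .data$band)
    perm <- with_seed(derive_seed(seed, "permute"),
                      sample(cow_band$band))
    cow_band$band <- perm
    ft$band <- NULL
    ft <- dplyr::left_join(ft, cow_band, by = "cow_id")
  }

  split <- grouped_split(ft, holdout_frac = holdout_frac, seed = seed)
  train <- ft[ft$event_id %in% split$train_event_ids, ]
  holdout <- ft[ft$event_id %in% split$holdout_event_ids, ]

  cv <- if (n_folds >= 2L) run_cv(train, spec, n_folds = n_folds,
                                  seed = seed) else NULL
  model <- fit_final(train, spec, seed = seed)
  report <- evaluate_holdout(model, holdout, n_boot = n_boot, seed = seed)

  structure(list(feature_table = ft, band_model = band_model,
                 split = split, cv = cv, model = model, report = report,
                 herd = dataset$herd),
            class = "weight_pipeline_run")
}

#' @export
print.weight_pipeline_run <- function(x, ...) {
  cat(sprintf("<weight_pipeline_run> %d events, %d bands\n",
              nrow(x$feature_table), x$band_model$n_bands))
  print(x$report)
  invisible(x)
}
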