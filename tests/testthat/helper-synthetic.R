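# Tabular fixtures for the classification harness: feature tables built
# directly (no rendering), with a controllable class signal.

make_toy_table <- function(n_cows, events_per_cow = 1L, n_classes = 3L,
                           signal = 5, noise = 1, seed = 1) {
  set.seed(seed)
  cow_band <- rep_len(seq_len(n_classes) - 1L, n_cows)
  rows <- list()
  for (i in seq_len(n_cows)) {
    b <- cow_band[i]
    for (e in seq_len(events_per_cow)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cow_id = sprintf("cow_%03d", i),
        event_id = sprintf("cow_%03d_e%d", i, e),
        band = b,
        x1 = b * signal + rnorm(1, 0, noise),
        x2 = b * signal * 0.5 + rnorm(1, 0, noise),
        x3 = rnorm(1),
        heart_girth_cm = 170 + b * 6 + rnorm(1, 0, noise)
      )
    }
  }
  dplyr::bind_rows(rows)
}

# the divisible capture-table layout: 270 cows x 4 events, 9 bands of
# exactly 30 cows -> a 20% grouped holdout of exactly 216 events exists
make_structured_1080 <- function(seed = 1) {
  tab <- make_toy_table(n_cows = 270L, events_per_cow = 4L, n_classes = 9L,
                        signal = 4, noise = 1, seed = seed)
  stopifnot(nrow(tab) == 1080L)
  tab
}
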