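#' Image-collection campaign metadata
#'
#' Per-batch bookkeeping for the multi-session data-collection campaign the
#' pipeline was designed around: twelve collection days grouped into nine
#' numbered rounds at the primary research herd, with image and animal counts
#' per occasion and whether complementary manual body measurements were
#' taken. Batches marked `lidar = TRUE` were captured with the
#' LiDAR-assisted mobile app; earlier batches used a laser distance meter.
#'
#' The table supports dataset-level sanity checks: total image count across
#' batches, total animal-sessions, and the single-batch subset (batch "9")
#' that feeds the weight-classification feature table.
#'
#' @return A tibble with columns `batch` (character label), `date`
#'   (character, month and year), `n_images`, `n_animals` (integers),
#'   `manual_measurements` and `lidar` (logical).
#' @examples
#' collection_batches() |> dplyr::summarise(total = sum(n_images))
#' @export
collection_batches <- function() {
  tibble::tribble(
    ~batch, ~date,                       ~n_images, ~n_animals, ~manual_measurements, ~lidar,
    "1a",   "May 2021",                  256L,      34L,        TRUE,  FALSE,
    "1b",   "May 2021",                  258L,      28L,        TRUE,  FALSE,
    "2",    "July 2021",                 55L,       22L,        TRUE,  FALSE,
    "3a",   "October-November 2021",     232L,      92L,        FALSE, FALSE,
    "3b",   "October-November 2021",     166L,      54L,        FALSE, FALSE,
    "3c",   "October-November 2021",     100L,      52L,        FALSE, FALSE,
    "4",    "October 2022",              14L,       5L,         FALSE, FALSE,
    "5",    "November 2022",             305L,      37L,        FALSE, FALSE,
    "6",    "November 2022",             125L,      25L,        FALSE, FALSE,
    "7",    "February 2023",             110L,      17L,        FALSE, FALSE,
    "8",    "May 2023",                  104L,      26L,        FALSE, TRUE,
    "9",    "December 2023",             1122L,     145L,       FALSE, TRUE
  )
}
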