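test_that("sample_herd validates inputs and honours the mixture", {
  expect_error(sample_herd(0), "integer")
  bad <- tibble::tibble(mean_kg = c(500, 600), sd_kg = 10, prop = c(0.5, 0.9))
  expect_error(sample_herd(10, weight_mixture = bad), "sum to 1")

  # vanishing variance pins every weight
  one <- tibble::tibble(mean_kg = 600, sd_kg = 1e-6, prop = 1)
  h <- sample_herd(100, weight_mixture = one, seed = 4)
  expect_true(all(abs(h$true_weight_kg - 600) < 0.01))

  # law of large numbers: empirical component means near truth
  mix3 <- tibble::tibble(mean_kg = c(500, 600, 700), sd_kg = 15, prop = 1 / 3)
  h3 <- sample_herd(3000, weight_mixture = mix3, seed = 7)
  comp <- c(500, 600, 700)[max.col(-abs(outer(h3$true_weight_kg,
                                              c(500, 600, 700), "-")))]
  for (m in c(500, 600, 700)) {
    n_m <- sum(comp == m)
    se <- 15 / sqrt(n_m)
    expect_lt(abs(mean(h3$true_weight_kg[comp == m]) - m), 3 * se + 1)
  }
})

test_that("herd body dimensions are non-decreasing in weight", {
  h <- sample_herd(200, seed = 2)
  o <- order(h$true_weight_kg)
  expect_true(all(diff(h$body_length_m[o]) >= 0))
  expect_true(all(diff(h$body_height_m[o]) >= 0))
  expect_true(all(h$heart_girth_cm >= 120 & h$heart_girth_cm <= 260))
})

test_that("girth link tracks the configured linear relation", {
  h <- sample_herd(800, girth_link = c(slope = 0.14, intercept = 120,
                                       noise_sd = 0), seed = 3)
  expect_equal(h$heart_girth_cm, 0.14 * h$true_weight_kg + 120,
               tolerance = 1e-12)
})

test_that("rendering is deterministic and produces one connected component", {
  cow <- sample_herd(1, seed = 10)
  m1 <- render_silhouette(cow, 2.0, pose_jitter = 0, seed = 5)
  m2 <- render_silhouette(cow, 2.0, pose_jitter = 0, seed = 5)
  expect_identical(m1, m2)
  expect_equal(max(EBImage::bwlabel(m1)), 1)
  # with jitter, same seed still reproduces exactly
  j1 <- render_silhouette(cow, 2.0, pose_jitter = 0.1, seed = 6)
  j2 <- render_silhouette(cow, 2.0, pose_jitter = 0.1, seed = 6)
  expect_identical(j1, j2)
})

test_that("projected size follows the pinhole relation", {
  cow <- sample_herd(1, seed = 11)
  big <- render_silhouette(cow, 1.0, canvas = c(1024L, 768L))
  small <- render_silhouette(cow, 2.0, canvas = c(1024L, 768L))
  expect_equal(sum(big) / sum(small), 4.0, tolerance = 0.05)

  # area x distance^2 constant across the working range
  areas <- vapply(seq(1.44, 2.72, length.out = 4), function(d) {
    sum(render_silhouette(cow, d, canvas = c(768L, 576L))) * d^2
  }, numeric(1))
  expect_lt(diff(range(areas)) / mean(areas), 0.05)
})

test_that("doubling body length doubles the projected width", {
  cow <- sample_herd(1, seed = 12)
  w1 <- extract_features(render_silhouette(cow, 2.0))$bbox_width_px
  cow2 <- cow
  cow2$body_length_m <- 2 * cow$body_length_m
  w2 <- extract_features(
    render_silhouette(cow2, 2.0, canvas = c(900L, 400L)))$bbox_width_px
  expect_equal(w2 / w1, 2.0, tolerance = 0.02)
})

test_that("an oversized projection errors with the required canvas size", {
  cow <- sample_herd(1, seed = 13)
  expect_error(render_silhouette(cow, 0.5, canvas = c(100L, 100L)),
               "needs at least")
})

test_that("perturb_mask is identity at severity 0 and degrades with severity", {
  cow <- sample_herd(1, seed = 14)
  m <- render_silhouette(cow, 2.0)
  expect_identical(perturb_mask(m, 0, seed = 1), m)
  expect_error(perturb_mask(m, 1.5), "severity")
  expect_lt(mask_f1(perturb_mask(m, 1, seed = 3), m), 1.0)

  f_low <- mean(vapply(1:60, function(s)
    mask_f1(perturb_mask(m, 0.2, seed = s), m), numeric(1)))
  f_high <- mean(vapply(1:60, function(s)
    mask_f1(perturb_mask(m, 0.8, seed = s), m), numeric(1)))
  expect_gt(f_low, f_high)
})

test_that("perturbation never grows the mask beyond the dilation bound", {
  cow <- sample_herd(1, seed = 15)
  m <- render_silhouette(cow, 2.0)
  grown <- EBImage::dilate(m, EBImage::makeBrush(3, "box"))
  for (s in 1:5) {
    p <- perturb_mask(m, 0.9, seed = s, max_dilate_px = 1L)
    expect_true(all(p <= as_binary_mask(grown)))
  }
})

test_that("generate_dataset bookkeeping and determinism", {
  ds <- generate_dataset(n_cows = 2, events_per_cow = 1,
                         images_per_event = 5, seed = 21)
  expect_equal(nrow(ds$captures), 10)
  expect_equal(nrow(ds$ground_truth), 2)
  expect_true(all(ds$captures$event_id %in% ds$ground_truth$event_id))

  ds2 <- generate_dataset(n_cows = 2, events_per_cow = 1,
                          images_per_event = 5, seed = 21)
  expect_identical(ds$captures$mask, ds2$captures$mask)
  expect_identical(ds$ground_truth, ds2$ground_truth)

  degen <- generate_dataset(n_cows = 2, events_per_cow = 2,
                            images_per_event = 1,
                            distance_range = c(2, 2),
                            distance_noise_sd = 0, seed = 22)
  expect_true(all(degen$ground_truth$distance_m == 2))
  expect_error(generate_dataset(0), "integer")
})

test_that("PNG round trip preserves masks and CSVs link images to truth", {
  ds <- generate_dataset(n_cows = 2, events_per_cow = 1,
                         images_per_event = 2, seed = 30)
  dir <- withr::local_tempdir()
  write_capture_dataset(ds, dir)
  meta <- utils::read.csv(file.path(dir, "captures.csv"))
  expect_equal(nrow(meta), 4)
  m <- read_mask_png(file.path(dir, meta$mask_file[1]))
  expect_identical(m, ds$captures$mask[[1]])
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  expect_setequal(gt$event_id, unique(meta$event_id))
})
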