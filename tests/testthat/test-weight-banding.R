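test_that("three well-separated clusters are recovered within 10 kg", {
  set.seed(41)
  w <- c(rnorm(200, 450, 20), rnorm(200, 600, 20), rnorm(200, 750, 20))
  m <- fit_weight_bands(w, seed = 1)
  expect_equal(m$n_bands, 3)
  expect_true(all(abs(m$means_kg - c(450, 600, 750)) < 10))
  expect_true(all(diff(m$means_kg) > 0))
})

test_that("sub-threshold components are absorbed (merge-rule oracle)", {
  set.seed(42)
  w <- c(rnorm(30, 500, 5), rnorm(30, 700, 5))
  m <- fit_weight_bands(w, seed = 1)
  expect_gte(m$k_selected, 3)  # search floor forces an overfit mixture
  expect_equal(m$n_bands, 2)
  expect_true(all(abs(sort(m$means_kg) - c(500, 700)) < 10))
  expect_gte(nrow(m$merge_log), 1)

  # exhaustive small-case check: every final band holds >= min_count
  for (s in 1:12) {
    set.seed(s)
    sizes <- sample(5:40, sample(2:4, 1), replace = TRUE)
    centres <- sort(sample(seq(400, 800, 50), length(sizes)))
    w <- unlist(mapply(function(n, mu) rnorm(n, mu, 4), sizes, centres,
                       SIMPLIFY = FALSE))
    fit <- fit_weight_bands(w, min_count = 25, seed = s)
    expect_true(all(fit$band_counts >= 25) || fit$n_bands == 1)
    expect_true(all(diff(fit$means_kg) > 0))
  }
})

test_that("degenerate data collapses to a single band", {
  m <- fit_weight_bands(rep(600, 100), seed = 1)
  expect_equal(m$n_bands, 1)
  expect_equal(m$means_kg, 600, tolerance = 1e-6)
})

test_that("input validation", {
  expect_error(fit_weight_bands(c(500, 600)), "at least")
  expect_error(fit_weight_bands(c(500, NA, 600, 700)), "finite")
  expect_error(fit_weight_bands(c(-5, 500, 600, 700)), "positive")
  expect_error(assign_bands(500, structure(list(), class = "lm")),
               "weight_band_model")
})

test_that("assignment is monotone and boundary ties go to the lower band", {
  set.seed(43)
  w <- c(rnorm(100, 500, 10), rnorm(100, 600, 10), rnorm(100, 700, 10))
  m <- fit_weight_bands(w, seed = 2)
  x <- sort(runif(500, 400, 800))
  lab <- assign_bands(x, m)
  expect_true(all(diff(lab) >= 0))
  # each band mean maps to its own label
  expect_equal(assign_bands(m$means_kg, m), seq_len(m$n_bands) - 1L)
  # training labels match the stored fit labels
  expect_identical(assign_bands(w, m), m$labels)
  # a point exactly on a boundary takes the lower label
  b <- m$boundaries_kg[1]
  expect_equal(assign_bands(b, m), assign_bands(b - 1e-9, m))
})

test_that("symmetric two-component posteriors cross at the midpoint", {
  # equal weights and sds: the interval boundary must be the mean midpoint
  set.seed(44)
  w <- c(rnorm(200, 500, 10), rnorm(200, 700, 10))
  m <- fit_weight_bands(w, k_min = 2, k_max = 2, min_count = 10, seed = 3)
  expect_equal(m$n_bands, 2)
  expect_equal(m$boundaries_kg, 600, tolerance = 5)
})

test_that("BIC uses 3K - 1 parameters and matches a direct recomputation", {
  set.seed(45)
  w <- c(rnorm(60, 480, 15), rnorm(60, 600, 15), rnorm(60, 720, 15))
  m <- fit_weight_bands(w, seed = 4)
  k <- m$k_selected
  dens <- vapply(seq_len(k), function(j) {
    m$premerge_weights[j] * dnorm(w, m$premerge_means_kg[j],
                                  m$premerge_sds_kg[j])
  }, numeric(length(w)))
  bic_direct <- -2 * sum(log(rowSums(dens))) + (3 * k - 1) * log(length(w))
  expect_equal(m$bic_trace$bic[m$bic_trace$k == k], bic_direct,
               tolerance = 1e-6)
})

test_that("banding selection agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  set.seed(46)
  w <- c(rnorm(150, 460, 12), rnorm(150, 600, 12), rnorm(150, 740, 12))
  ours <- fit_weight_bands(w, seed = 5)
  mclustBIC <- mclust::mclustBIC  # Mclust looks it up unqualified
  mc <- mclust::Mclust(w, G = 3:10, modelNames = "V", verbose = FALSE)
  expect_equal(ours$k_selected, mc$G)
  expect_equal(sort(ours$means_kg), sort(as.numeric(mc$parameters$mean)),
               tolerance = 5)
})

test_that("tidy/glance/autoplot methods expose the fit", {
  set.seed(47)
  w <- c(rnorm(100, 500, 10), rnorm(100, 650, 10))
  m <- fit_weight_bands(w, min_count = 20, seed = 6)
  td <- tidy(m)
  expect_equal(nrow(td), m$n_bands)
  expect_true(all(diff(td$mean_kg) > 0))
  expect_equal(sum(td$n), length(w))
  gl <- glance(m)
  expect_equal(gl$n_obs, 200)
  expect_s3_class(autoplot(m, weights_kg = w), "ggplot")
})

test_that("nine-band structure is recovered across seeded replicates", {
  mix <- tibble::tibble(mean_kg = seq(420, 740, 40), sd_kg = 6, prop = 1 / 9)
  n_bands <- vapply(1:10, function(s) {
    h <- sample_herd(405, weight_mixture = mix, seed = 100 + s)
    fit_weight_bands(h$true_weight_kg, seed = s)$n_bands
  }, numeric(1))
  expect_gte(mean(n_bands == 9), 0.9)
})
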