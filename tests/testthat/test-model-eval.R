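test_that("aggregate_burst is the per-feature median with image count", {
  one <- tibble::tibble(cow_id = "a", event_id = "a_e1", image_index = 1L,
                        mask_area_mm2 = 5, extent = 0.7)
  agg <- aggregate_burst(one)
  expect_equal(agg$mask_area_mm2, 5)
  expect_equal(agg$n_images, 1L)

  five <- one[rep(1, 5), ]
  five$image_index <- 1:5
  agg5 <- aggregate_burst(five)
  expect_equal(nrow(agg5), 1)
  expect_equal(agg5$mask_area_mm2, 5)
  expect_equal(agg5$n_images, 5L)

  # median shrugs off one corrupted mask in the burst
  burst <- one[rep(1, 5), ]
  burst$image_index <- 1:5
  burst$mask_area_mm2 <- c(1, 2, 100, 2, 1)
  expect_equal(aggregate_burst(burst)$mask_area_mm2, 2)
  expect_error(aggregate_burst(one[0, ]), "No feature rows")
})

test_that("grouped_split keeps cows whole and hits attainable targets", {
  tab <- make_toy_table(10, n_classes = 2, seed = 1)
  sp <- grouped_split(tab, holdout_frac = 0.2, seed = 1)
  expect_length(sp$holdout_event_ids, 2)
  cows_h <- unique(tab$cow_id[tab$event_id %in% sp$holdout_event_ids])
  cows_t <- unique(tab$cow_id[tab$event_id %in% sp$train_event_ids])
  expect_length(intersect(cows_h, cows_t), 0)

  for (s in 1:10) {
    tab2 <- make_toy_table(23, events_per_cow = 3, n_classes = 4, seed = s)
    sp2 <- grouped_split(tab2, holdout_frac = 0.25, seed = s)
    ch <- unique(tab2$cow_id[tab2$event_id %in% sp2$holdout_event_ids])
    ct <- unique(tab2$cow_id[tab2$event_id %in% sp2$train_event_ids])
    expect_length(intersect(ch, ct), 0)
    expect_setequal(c(sp2$train_event_ids, sp2$holdout_event_ids),
                    tab2$event_id)
  }
  expect_error(grouped_split(make_toy_table(1), 0.2), "two cows")
})

test_that("the divisible 1080-event table yields a 216-event holdout", {
  tab <- make_structured_1080(seed = 3)
  sp <- grouped_split(tab, holdout_frac = 0.2, seed = 3)
  expect_length(sp$holdout_event_ids, 216)
  # and the holdout preserves the band distribution exactly
  hold <- tab[tab$event_id %in% sp$holdout_event_ids, ]
  expect_true(all(table(hold$band) == 24))
})

test_that("SMOTE balances classes inside training data only", {
  X <- data.frame(a = c(rnorm(20), rnorm(5, 5)), b = rnorm(25))
  y <- rep(c("0", "1"), c(20, 5))
  sm <- cowbands:::smote_oversample(X, y, k_neighbors = 3, seed = 1)
  expect_equal(as.integer(table(sm$y)), c(20, 20))
  expect_equal(sum(sm$synthetic), 15)
  expect_equal(nrow(sm$X), 40)
  # synthetic points interpolate within the minority class range
  syn <- sm$X[sm$synthetic, "a"]
  expect_true(all(syn >= min(X$a[21:25]) - 1e-9 &
                    syn <= max(X$a[21:25]) + 1e-9))
  # singleton class duplicates
  sm1 <- cowbands:::smote_oversample(X[1:21, ], rep(c("0", "1"), c(20, 1)),
                                     seed = 2)
  expect_equal(as.integer(table(sm1$y)), c(20, 20))
})

test_that("a separable table is fit perfectly and probabilities sum to 1", {
  tab <- make_toy_table(30, n_classes = 3, signal = 10, noise = 0.1,
                        seed = 11)
  model <- fit_final(tab, pipeline_spec(), seed = 1)
  expect_equal(predict(model, tab), tab$band)
  pr <- predict(model, tab, type = "prob")
  expect_true(all(abs(rowSums(pr) - 1) < 1e-9))
  expect_equal(colnames(pr), c("0", "1", "2"))
  expect_error(predict(model, tab[, c("cow_id", "band")]), "missing")
})

test_that("grouped CV is leak-free and perfect on separable data", {
  tab <- make_toy_table(30, events_per_cow = 2, n_classes = 3, signal = 10,
                        noise = 0.1, seed = 12)
  cv <- run_cv(tab, pipeline_spec(), n_folds = 5, seed = 2)
  expect_equal(nrow(cv), 5)
  expect_equal(attr(cv, "summary")$macro_f1, 1.0)
  folds <- attr(cv, "folds")
  expect_equal(anyDuplicated(folds$cow_id), 0)  # each cow in one fold
})

test_that("permuted labels fall to chance level in grouped CV", {
  tab <- make_toy_table(90, n_classes = 3, signal = 10, noise = 0.1,
                        seed = 13)
  set.seed(13)
  tab$band <- sample(tab$band)
  cv <- run_cv(tab, pipeline_spec(n_trees = 200L), n_folds = 3, seed = 3)
  expect_lt(attr(cv, "summary")$macro_f1, 1 / 3 + 0.2)
})

test_that("leakage audit: no cow crossings, no SMOTE rows outside training", {
  for (s in 1:20) {
    tab <- make_toy_table(20, events_per_cow = 2, n_classes = 3, seed = s)
    sp <- grouped_split(tab, 0.2, seed = s)
    train <- tab[tab$event_id %in% sp$train_event_ids, ]
    hold <- tab[tab$event_id %in% sp$holdout_event_ids, ]
    expect_length(intersect(unique(train$cow_id), unique(hold$cow_id)), 0)
    model <- fit_final(train, pipeline_spec(n_trees = 50L), seed = s)
    # the model saw exactly the training events, never holdout ids
    expect_setequal(model$train_event_ids, sp$train_event_ids)
    expect_length(intersect(model$train_event_ids, hold$event_id), 0)
    # oversampled rows exist only inside the fitted model's augmentation
    expect_equal(model$n_synthetic,
                 sum(model$smote_info$n_synthetic))
    expect_equal(nrow(hold),
                 length(sp$holdout_event_ids))  # holdout untouched
  }
})

test_that("ordinal decomposition matches hand enumeration and partitions", {
  d <- ordinal_decomposition(0:4, c(0, 2, 2, 3, 1))
  expect_equal(d$error_rate, 0.4)
  expect_equal(d$adjacent_rate, 0.2)
  expect_equal(d$nonadjacent_rate, 0.2)
  expect_equal(d$dist_mean, 0.8)
  expect_equal(d$dist_median, 0)
  expect_equal(d$dist_max, 3)

  perfect <- ordinal_decomposition(1:5, 1:5)
  expect_equal(perfect$error_rate, 0)
  expect_equal(perfect$dist_max, 0)

  set.seed(14)
  for (i in 1:20) {
    yt <- sample(0:8, 40, TRUE); yp <- sample(0:8, 40, TRUE)
    dd <- ordinal_decomposition(yt, yp)
    expect_equal(dd$adjacent_rate + dd$nonadjacent_rate, dd$error_rate)
    expect_gte(dd$dist_max, dd$dist_mean)
  }
})

test_that("F1 metrics agree with brute-force recomputation", {
  set.seed(15)
  for (i in 1:10) {
    yt <- sample(0:3, 20, TRUE); yp <- sample(0:3, 20, TRUE)
    cls <- sort(unique(c(yt, yp)))
    f1s <- sapply(cls, function(cl) {
      tp <- sum(yt == cl & yp == cl)
      prec <- if (sum(yp == cl) == 0) NA else tp / sum(yp == cl)
      rec <- if (sum(yt == cl) == 0) NA else tp / sum(yt == cl)
      if (is.na(prec) || is.na(rec) || prec + rec == 0) 0
      else 2 * prec * rec / (prec + rec)
    })
    expect_equal(macro_f1(yt, yp), mean(f1s))
    expect_equal(weighted_f1(yt, yp),
                 sum(f1s * table(factor(yt, levels = cls))) / length(yt))
    expect_equal(accuracy(yt, yp), mean(yt == yp))
  }
})

test_that("bootstrap CI behaves as a percentile interval", {
  y <- rep(0:2, each = 10)
  ci <- bootstrap_ci(y, y, n_reps = 200, seed = 1)
  expect_equal(ci$low, 1.0)
  expect_equal(ci$high, 1.0)

  set.seed(16)
  yp <- y; yp[sample(30, 6)] <- sample(0:2, 6, TRUE)
  ci2 <- bootstrap_ci(y, yp, n_reps = 500, seed = 2)
  point <- macro_f1(y, yp)
  expect_lte(ci2$low, point)
  expect_gte(ci2$high, point)

  ci3 <- bootstrap_ci(y, yp, n_reps = 1000, seed = 2)
  expect_lt(abs(ci3$low - ci2$low), 0.02)
  expect_lt(abs(ci3$high - ci2$high), 0.02)
  # reproducible under the same seed
  ci4 <- bootstrap_ci(y, yp, n_reps = 500, seed = 2)
  expect_identical(ci2[c("low", "high")], ci4[c("low", "high")])
})

test_that("Brier score closed forms", {
  onehot <- diag(3)[c(1, 2, 3), ]
  colnames(onehot) <- 0:2
  expect_equal(multiclass_brier(onehot, c(0, 1, 2)), 0)
  expect_equal(multiclass_brier(onehot, c(1, 2, 0)), 2)
  unif9 <- matrix(1 / 9, 4, 9)
  expect_equal(multiclass_brier(unif9, c(0, 3, 5, 8)), 8 / 9)
  expect_error(multiclass_brier(matrix(c(0.5, 0.4), 1, 2), 0), "sum to 1")
})

test_that("ECE closed forms and bounds", {
  onehot <- diag(4); colnames(onehot) <- 0:3
  expect_equal(expected_calibration_error(onehot, 0:3)$ece, 0)

  confident <- matrix(rep(c(1, 0), each = 0), 0, 0)
  p <- matrix(0, 10, 2, dimnames = list(NULL, 0:1)); p[, 1] <- 1
  y <- rep(0:1, each = 5)  # always predicts 0 at confidence 1, 50% right
  expect_equal(expected_calibration_error(p, y)$ece, 0.5)

  set.seed(17)
  pr <- matrix(runif(40 * 3), 40, 3); pr <- pr / rowSums(pr)
  colnames(pr) <- 0:2
  res <- expected_calibration_error(pr, sample(0:2, 40, TRUE))
  expect_gte(res$ece, 0)
  expect_lte(res$ece, 1)
  expect_equal(sum(res$reliability_bins$count), 40)
})

test_that("mask F1 closed forms", {
  truth <- matrix(0L, 10, 20); truth[1:10, 1:20] <- 1L
  pred <- matrix(0L, 10, 20); pred[1:10, 1:10] <- 1L
  expect_equal(mask_f1(truth, truth), 1)
  expect_equal(mask_f1(pred, truth), 2 / 3)
  disjoint <- matrix(0L, 10, 20)
  expect_equal(mask_f1(disjoint + 0L, truth), 0)
  expect_error(mask_f1(matrix(0L, 2, 2), truth), "dimensions")
})

test_that("evaluate_holdout refuses leaking rows and reports coherently", {
  tab <- make_toy_table(40, n_classes = 4, signal = 8, noise = 0.5,
                        seed = 18)
  sp <- grouped_split(tab, 0.25, seed = 18)
  train <- tab[tab$event_id %in% sp$train_event_ids, ]
  hold <- tab[tab$event_id %in% sp$holdout_event_ids, ]
  model <- fit_final(train, pipeline_spec(n_trees = 100L), seed = 1)
  expect_error(evaluate_holdout(model, train), "leak")
  rep <- evaluate_holdout(model, hold, n_boot = 200, seed = 1)
  gl <- glance(rep)
  expect_equal(gl$adjacent_rate + gl$nonadjacent_rate, gl$error_rate)
  expect_equal(gl$accuracy, 1 - gl$error_rate)
  expect_lte(gl$ci_low, gl$macro_f1 + 1e-9)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_equal(sum(rep$confusion), nrow(hold))
})
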