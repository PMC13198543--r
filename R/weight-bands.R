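# Data-driven weight discretisation: a one-dimensional Gaussian mixture is
# fitted for each candidate component count, the count is chosen by BIC,
# components too small to act as a weight band are merged into their
# nearest neighbour in mean weight, and the surviving components are
# converted to contiguous ordered intervals.

# n x k matrix of log(w_j) + log N(x_i; mu_j, sigma2_j), fully vectorised.
gmm_log_dens <- function(x, w, mu, sigma2) {
  d2 <- outer(x, mu, "-")^2
  sweep(-0.5 * sweep(d2, 2L, sigma2, "/"), 2L,
        log(w) - 0.5 * log(2 * pi * sigma2), "+")
}

row_max <- function(m) do.call(pmax, as.data.frame(m))

gmm_loglik <- function(x, w, mu, sigma2) {
  logp <- gmm_log_dens(x, w, mu, sigma2)
  m <- row_max(logp)
  sum(m + log(rowSums(exp(logp - m))))
}

gmm_em_once <- function(x, mu0, sigma2_0, w0, var_floor,
                        tol = 1e-6, max_iter = 300L) {
  n <- length(x)
  mu <- mu0; sigma2 <- pmax(sigma2_0, var_floor); w <- w0 / sum(w0)
  ll_old <- -Inf; ll <- -Inf
  for (iter in seq_len(max_iter)) {
    logp <- gmm_log_dens(x, w, mu, sigma2)
    m <- row_max(logp)
    li <- m + log(rowSums(exp(logp - m)))
    ll <- sum(li)
    r <- exp(logp - li)  # responsibilities
    nk <- pmax(colSums(r), 1e-12)
    w <- nk / n
    mu <- colSums(r * x) / nk
    sigma2 <- pmax(colSums(r * outer(x, mu, "-")^2) / nk, var_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(w = w, mu = mu, sigma2 = sigma2, loglik = ll)
}

fit_gmm_1d <- function(x, k, n_restarts = 5L, var_floor, seed = 1L) {
  qs <- quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  inits <- list(list(mu = qs, sigma2 = rep(max(var(x), var_floor) / k^2, k)))
  if (n_restarts > 0) {
    extra <- with_seed(derive_seed(seed, paste0("gmm_init_k", k)), {
      lapply(seq_len(n_restarts), function(i) {
        list(mu = sort(sample(x, k)),
             sigma2 = rep(max(var(x), var_floor), k))
      })
    })
    inits <- c(inits, extra)
  }
  best <- NULL
  for (init in inits) {
    fit <- gmm_em_once(x, init$mu, pmax(init$sigma2, var_floor),
                       rep(1 / k, k), var_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

# Posterior-equality crossover between two adjacent weighted normals;
# falls back to the sd-weighted midpoint if no sign change is bracketed.
component_boundary <- function(w1, mu1, s2_1, w2, mu2, s2_2) {
  if (mu2 - mu1 < 1e-12) return((mu1 + mu2) / 2)
  f <- function(x) {
    (log(w1) + dnorm(x, mu1, sqrt(s2_1), log = TRUE)) -
      (log(w2) + dnorm(x, mu2, sqrt(s2_2), log = TRUE))
  }
  lo <- mu1; hi <- mu2
  if (!is.finite(f(lo)) || !is.finite(f(hi)) || f(lo) * f(hi) > 0) {
    s1 <- sqrt(s2_1); s2 <- sqrt(s2_2)
    return((mu1 * s2 + mu2 * s1) / (s1 + s2))
  }
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

band_boundaries <- function(w, mu, sigma2) {
  k <- length(mu)
  if (k < 2L) return(numeric(0))
  vapply(seq_len(k - 1L), function(i) {
    component_boundary(w[i], mu[i], sigma2[i], w[i + 1], mu[i + 1],
                       sigma2[i + 1])
  }, numeric(1))
}

# Interval membership: label = number of boundaries strictly below x, so a
# point exactly on a boundary takes the lower label (documented tie-break).
interval_labels <- function(x, boundaries) {
  if (length(boundaries) == 0L) return(rep(0L, length(x)))
  as.integer(rowSums(outer(x, boundaries, ">")))
}

#' Fit data-driven weight bands (1-D Gaussian mixture + BIC + merging)
#'
#' Fits a one-dimensional Gaussian mixture to body weights for each
#' component count `K` in `k_min:k_max` by EM (quantile initialisation plus
#' random restarts, variance floor `1e-6 * var(x)`), selects `K` by
#' minimising `BIC = -2 logL + (3K - 1) log n`, then iteratively merges any
#' component holding fewer than `min_count` observations — smallest first —
#' into the surviving component with the nearest mean, pooling means and
#' variances. The surviving components, ordered by mean, define contiguous
#' weight intervals whose cut points are the posterior-equality crossovers
#' between adjacent components, giving ordinal band labels `0, 1, ...` with
#' strictly increasing mean weight.
#'
#' @param weights_kg Numeric vector of positive body weights (kg).
#' @param k_min,k_max Component-count search range (defaults 3 and 10).
#' @param min_count Minimum observations per final band (default 25).
#' @param n_restarts Random EM restarts per `K` beyond the quantile start.
#' @param seed Integer seed for the restarts.
#' @return An object of class `"weight_band_model"` with elements
#'   `k_selected`, `bic_trace` (tibble `k`, `bic`), pre-merge parameters,
#'   final `means_kg`, `sds_kg`, `weights` (sorted by mean), `boundaries_kg`,
#'   `merge_log` (tibble of absorbed/absorbing means), `n_bands`,
#'   `band_counts`, and `labels` (the fitting data's band labels).
#' @examples
#' w <- c(rnorm(60, 480, 15), rnorm(60, 600, 15), rnorm(60, 720, 15))
#' m <- fit_weight_bands(w, seed = 1)
#' m$n_bands
#' @export
fit_weight_bands <- function(weights_kg, k_min = 3L, k_max = 10L,
                             min_count = 25L, n_restarts = 5L, seed = 1L) {
  x <- as.numeric(weights_kg)
  if (length(x) == 0L || any(!is.finite(x))) {
    abort("`weights_kg` must be finite and non-empty.")
  }
  if (any(x <= 0)) abort("`weights_kg` must be positive.")
  k_min <- check_count(k_min, "k_min"); k_max <- check_count(k_max, "k_max")
  min_count <- check_count(min_count, "min_count")
  if (k_max < k_min) abort("`k_max` must be >= `k_min`.")
  if (length(x) < k_min) {
    abort(sprintf("Need at least k_min = %d observations, got %d.",
                  k_min, length(x)))
  }
  n <- length(x)
  vx <- var(x)
  var_floor <- max(1e-6 * ifelse(is.finite(vx) && vx > 0, vx, 1),
                   .Machine$double.eps)

  fits <- list(); bic <- numeric(0)
  for (k in k_min:k_max) {
    fit <- fit_gmm_1d(x, k, n_restarts = n_restarts, var_floor = var_floor,
                      seed = seed)
    fits[[as.character(k)]] <- fit
    bic <- c(bic, -2 * fit$loglik + (3 * k - 1) * log(n))
  }
  ks <- k_min:k_max
  k_sel <- ks[which.min(bic)]
  fit <- fits[[as.character(k_sel)]]

  ord <- order(fit$mu)
  w <- fit$w[ord]; mu <- fit$mu[ord]; s2 <- fit$sigma2[ord]

  merge_log <- list()
  repeat {
    counts <- tabulate(interval_labels(x, band_boundaries(w, mu, s2)) + 1L,
                       nbins = length(mu))
    small <- which(counts < min_count)
    if (length(small) == 0L || length(mu) == 1L) break
    # absorb the currently smallest component (ties: lowest mean)
    j <- small[which.min(counts[small])]
    others <- setdiff(seq_along(mu), j)
    tgt <- others[which.min(abs(mu[others] - mu[j]))]
    merge_log[[length(merge_log) + 1L]] <- tibble::tibble(
      absorbed_mean_kg = mu[j], absorbing_mean_kg = mu[tgt],
      absorbed_count = counts[j])
    wt <- w[j] + w[tgt]
    mu_new <- (w[j] * mu[j] + w[tgt] * mu[tgt]) / wt
    s2_new <- (w[j] * (s2[j] + mu[j]^2) + w[tgt] * (s2[tgt] + mu[tgt]^2)) /
      wt - mu_new^2
    w[tgt] <- wt; mu[tgt] <- mu_new; s2[tgt] <- max(s2_new, var_floor)
    w <- w[-j]; mu <- mu[-j]; s2 <- s2[-j]
    ord <- order(mu)
    w <- w[ord]; mu <- mu[ord]; s2 <- s2[ord]
  }

  boundaries <- band_boundaries(w, mu, s2)
  labels <- interval_labels(x, boundaries)
  structure(list(
    k_selected = k_sel,
    bic_trace = tibble::tibble(k = ks, bic = bic),
    premerge_means_kg = fit$mu[order(fit$mu)],
    premerge_sds_kg = sqrt(fit$sigma2[order(fit$mu)]),
    premerge_weights = fit$w[order(fit$mu)],
    means_kg = mu, sds_kg = sqrt(s2), weights = w,
    boundaries_kg = boundaries,
    merge_log = if (length(merge_log)) dplyr::bind_rows(merge_log) else
      tibble::tibble(absorbed_mean_kg = numeric(0),
                     absorbing_mean_kg = numeric(0),
                     absorbed_count = integer(0)),
    n_bands = length(mu),
    band_counts = tabulate(labels + 1L, nbins = length(mu)),
    min_count = min_count,
    n_obs = n,
    labels = labels
  ), class = "weight_band_model")
}

#' Assign weight-band labels
#'
#' Maps weights to the ordinal band labels of a fitted
#' [fit_weight_bands()] model by interval membership. Labels are
#' non-decreasing in weight; a weight exactly on a boundary takes the lower
#' label.
#'
#' @param weights_kg Numeric vector of weights (kg).
#' @param model A `"weight_band_model"`.
#' @return Integer labels in `0:(n_bands - 1)`.
#' @export
assign_bands <- function(weights_kg, model) {
  if (!inherits(model, "weight_band_model")) {
    abort("`model` must be a fitted weight_band_model.")
  }
  x <- as.numeric(weights_kg)
  if (any(!is.finite(x))) abort("`weights_kg` must be finite.")
  interval_labels(x, model$boundaries_kg)
}

#' @export
print.weight_band_model <- function(x, ...) {
  cat(sprintf(
    "<weight_band_model> K = %d by BIC, %d band(s) after merging %d component(s)\n",
    x$k_selected, x$n_bands, nrow(x$merge_log)))
  cat("band means (kg):", paste(sprintf("%.0f", x$means_kg), collapse = ", "),
      "\n")
  invisible(x)
}

#' @describeIn fit_weight_bands One row per final band: label, mean, sd,
#'   mixture weight, member count, and interval bounds.
#' @param x A `"weight_band_model"`.
#' @param ... Unused.
#' @export
tidy.weight_band_model <- function(x, ...) {
  nb <- x$n_bands
  lower <- c(-Inf, x$boundaries_kg)
  upper <- c(x$boundaries_kg, Inf)
  tibble::tibble(
    band = seq_len(nb) - 1L,
    mean_kg = x$means_kg, sd_kg = x$sds_kg, weight = x$weights,
    n = x$band_counts, lower_kg = lower, upper_kg = upper
  )
}

#' @describeIn fit_weight_bands One-row model summary.
#' @export
glance.weight_band_model <- function(x, ...) {
  tibble::tibble(
    k_selected = x$k_selected, n_bands = x$n_bands,
    n_merged = nrow(x$merge_log), n_obs = x$n_obs,
    bic = min(x$bic_trace$bic)
  )
}

#' @describeIn fit_weight_bands Weight histogram with fitted band density
#'   and interval boundaries.
#' @param object A `"weight_band_model"`.
#' @param weights_kg Optional weights to histogram (defaults to densities
#'   only).
#' @export
autoplot.weight_band_model <- function(object, weights_kg = NULL, ...) {
  rng <- range(object$means_kg) + c(-4, 4) * max(object$sds_kg)
  grid <- seq(rng[1], rng[2], length.out = 400)
  dens <- purrr::map_dfr(seq_len(object$n_bands), function(k) {
    tibble::tibble(
      band = factor(k - 1L), weight_kg = grid,
      density = object$weights[k] *
        dnorm(grid, object$means_kg[k], object$sds_kg[k]))
  })
  p <- ggplot2::ggplot()
  if (!is.null(weights_kg)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(weight_kg = weights_kg),
      ggplot2::aes(x = .data$weight_kg, y = ggplot2::after_stat(density)),
      bins = 40, fill = "grey85", colour = "grey60")
  }
  p +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(x = .data$weight_kg, y = .data$density,
                                    colour = .data$band)) +
    ggplot2::geom_vline(xintercept = object$boundaries_kg,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "body weight (kg)", y = "density",
                  colour = "band")
}
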