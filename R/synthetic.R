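# Synthetic herd and silhouette generator.
#
# The generator emulates the statistical structure the analysis assumes:
# a herd with multimodal weight structure (9 components by default, enough
# members per band), heart girth linearly linked to weight (cohort average
# near 200 cm), burst captures of five images per event at stand-off
# distances 1.44-2.72 m, and segmentation noise in the form of appendage
# dropout and boundary flicker.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

default_weight_mixture <- function() {
  tibble::tibble(mean_kg = seq(420, 740, by = 40), sd_kg = 6, prop = 1 / 9)
}

# Heart girth from weight: girth = slope * weight + intercept + N(0, sd).
# Defaults invert the classical mixed-breed girth-only weight equation
# (BW = HG * 7.3827 - 878.3134), so a 600 kg cow averages ~200 cm.
default_girth_link <- function() {
  c(slope = 1 / 7.3827, intercept = 878.3134 / 7.3827, noise_sd = 2.0)
}

check_weight_mixture <- function(weight_mixture) {
  wm <- tibble::as_tibble(weight_mixture)
  if (!all(c("mean_kg", "sd_kg", "prop") %in% names(wm)) || nrow(wm) == 0) {
    abort("`weight_mixture` needs columns mean_kg, sd_kg, prop.")
  }
  if (any(wm$sd_kg <= 0) || any(wm$mean_kg <= 0) || any(wm$prop < 0)) {
    abort("`weight_mixture` components must have positive means/sds and non-negative proportions.")
  }
  if (abs(sum(wm$prop) - 1) > 1e-6) {
    abort("`weight_mixture` proportions must sum to 1.")
  }
  wm
}

# Allometry: linear body dimensions scale with weight^(1/3), anchored at a
# 600 kg reference cow of 1.70 m body length and 1.45 m height.
body_dims_from_weight <- function(weight_kg) {
  s <- (weight_kg / 600)^(1 / 3)
  list(body_length_m = 1.70 * s, body_height_m = 1.45 * s)
}

#' Sample a synthetic herd
#'
#' Draws cow weights from a Gaussian mixture (one component per intended
#' weight band), links heart girth to weight by a linear relation plus
#' measurement noise, and derives body dimensions from weight by an
#' allometric power law (linear dimension proportional to weight^(1/3)).
#'
#' @param n_cows Number of cows.
#' @param weight_mixture Tibble with columns `mean_kg`, `sd_kg`, `prop`
#'   describing the herd's weight mixture; proportions must sum to 1. The
#'   default is nine equally likely components 40 kg apart (420-740 kg).
#' @param girth_link Named vector `c(slope, intercept, noise_sd)`:
#'   `heart_girth_cm = slope * weight + intercept + N(0, noise_sd)`. The
#'   default inverts the classical mixed-breed girth-only equation, so the
#'   cohort girth averages about 200 cm.
#' @param girth_range Plausible heart-girth range in cm; draws are clamped.
#' @param seed Integer seed; identical seeds give identical herds.
#' @return A tibble with columns `cow_id`, `breed_tag`, `true_weight_kg`,
#'   `heart_girth_cm`, `body_length_m`, `body_height_m`.
#' @examples
#' sample_herd(5, seed = 1)
#' @export
sample_herd <- function(n_cows,
                        weight_mixture = default_weight_mixture(),
                        girth_link = default_girth_link(),
                        girth_range = c(120, 260),
                        seed = 1L) {
  n_cows <- check_count(n_cows, "n_cows")
  wm <- check_weight_mixture(weight_mixture)
  if (length(girth_link) != 3L || any(!is.finite(girth_link)) ||
      girth_link[[3]] < 0) {
    abort("`girth_link` must be c(slope, intercept, noise_sd >= 0).")
  }
  with_seed(derive_seed(seed, "herd"), {
    comp <- sample.int(nrow(wm), n_cows, replace = TRUE, prob = wm$prop)
    w <- rnorm(n_cows, wm$mean_kg[comp], wm$sd_kg[comp])
    w <- pmax(w, 1)
    hg <- girth_link[[1]] * w + girth_link[[2]] +
      rnorm(n_cows, 0, girth_link[[3]])
    hg <- pmin(pmax(hg, girth_range[1]), girth_range[2])
    breed <- sample(c("SR", "SH"), n_cows, replace = TRUE, prob = c(0.6, 0.4))
    dims <- body_dims_from_weight(w)
    tibble::tibble(
      cow_id = sprintf("cow_%04d", seq_len(n_cows)),
      breed_tag = breed,
      true_weight_kg = w,
      heart_girth_cm = hg,
      body_length_m = dims$body_length_m,
      body_height_m = dims$body_height_m
    )
  })
}

# Analytic cow silhouette in world coordinates (metres): ellipse torso,
# four rectangular legs, elliptical head, thin hanging tail. x runs along
# the body (head at +x), y up from the ground.
cow_shape_params <- function(bl, bh, jitter = c(0, 0, 0)) {
  list(
    torso_c = c(0, 0.62 * bh), torso_ab = c(0.44 * bl, 0.30 * bh),
    leg_xc = c(-0.33, -0.18, 0.18, 0.33) * bl,
    leg_halfw = 0.027 * bl, leg_top = 0.45 * bh,
    head_c = c(0.52 * bl, (0.70 + 0.2 * jitter[2]) * bh),
    head_ab = c(0.12 * bl, 0.10 * bh),
    tail_x = c(-0.48, -0.43) * bl,
    tail_y = c(0.30 * bh, 0.66 * bh),
    theta = jitter[1]
  )
}

inside_cow <- function(x, y, p) {
  # rotate into body frame about the torso centre
  if (p$theta != 0) {
    dx <- x - p$torso_c[1]; dy <- y - p$torso_c[2]
    ct <- cos(-p$theta); st <- sin(-p$theta)
    x <- p$torso_c[1] + ct * dx - st * dy
    y <- p$torso_c[2] + st * dx + ct * dy
  }
  inside <- ((x - p$torso_c[1]) / p$torso_ab[1])^2 +
    ((y - p$torso_c[2]) / p$torso_ab[2])^2 <= 1
  for (xc in p$leg_xc) {
    inside <- inside | (abs(x - xc) <= p$leg_halfw & y >= 0 & y <= p$leg_top)
  }
  inside <- inside | ((x - p$head_c[1]) / p$head_ab[1])^2 +
    ((y - p$head_c[2]) / p$head_ab[2])^2 <= 1
  inside <- inside | (x >= p$tail_x[1] & x <= p$tail_x[2] &
                        y >= p$tail_y[1] & y <= p$tail_y[2])
  inside
}

#' Render a synthetic cow silhouette
#'
#' Rasterises the analytic cow shape (ellipse torso, four legs, head, tail)
#' onto a pixel canvas under the pinhole relation: apparent size is
#' proportional to body dimension over distance. A pixel is foreground when
#' its centre lies inside the analytic shape, so rendering is deterministic
#' given cow, distance, jitter draws, and seed.
#'
#' @param cow A one-row herd tibble (see [sample_herd()]), or any list with
#'   `body_length_m` and `body_height_m`.
#' @param distance_m Camera-to-animal distance in metres.
#' @param pose_jitter Non-negative severity of pose variation (body-axis
#'   rotation and head-height jitter); 0 disables it.
#' @param canvas `c(width_px, height_px)` of the raster.
#' @param focal_px_m Pinhole scale constant: an object of physical length L
#'   metres at distance d spans `L * focal_px_m / d` pixels.
#' @param seed Integer seed for the jitter draws.
#' @return A 0/1 integer matrix of size `canvas[2]` x `canvas[1]`.
#' @examples
#' cow <- sample_herd(1, seed = 3)
#' mask <- render_silhouette(cow, distance_m = 2.0)
#' sum(mask)
#' @export
render_silhouette <- function(cow, distance_m, pose_jitter = 0,
                              canvas = c(384L, 288L), focal_px_m = 240,
                              seed = 1L) {
  check_positive_scalar(distance_m, "distance_m")
  if (pose_jitter < 0) abort("`pose_jitter` must be non-negative.")
  bl <- cow$body_length_m[[1]]; bh <- cow$body_height_m[[1]]
  stopifnot(is.finite(bl), is.finite(bh), bl > 0, bh > 0)
  jit <- if (pose_jitter > 0) {
    with_seed(derive_seed(seed, "pose"), rnorm(3) * pose_jitter)
  } else {
    c(0, 0, 0)
  }
  p <- cow_shape_params(bl, bh, jit)
  px_per_m <- focal_px_m / distance_m
  wpx <- as.integer(canvas[1]); hpx <- as.integer(canvas[2])
  need_w <- ceiling(1.15 * bl * px_per_m) + 8L
  need_h <- ceiling(0.95 * bh * px_per_m) + 12L
  if (need_w > wpx || need_h > hpx) {
    abort(sprintf(
      "Projected body exceeds the %dx%d canvas; at %.2f m it needs at least %dx%d px.",
      wpx, hpx, distance_m, need_w, need_h))
  }
  margin_px <- 4
  # pixel centres in world coordinates; ground sits margin_px above bottom
  xw <- ((seq_len(wpx) - 0.5) - wpx / 2) / px_per_m
  yw <- ((hpx - seq_len(hpx) + 0.5) - margin_px) / px_per_m
  xg <- matrix(xw, nrow = hpx, ncol = wpx, byrow = TRUE)
  yg <- matrix(yw, nrow = hpx, ncol = wpx)
  matrix(as.integer(inside_cow(xg, yg, p)), nrow = hpx, ncol = wpx)
}

#' Apply synthetic segmentation noise to a mask
#'
#' Emulates the two segmentation failure modes seen with real barn imagery:
#' variable inclusion of extremities (thin appendages — legs, tail, head
#' margin — vanish from the mask) and boundary flicker (single boundary
#' pixels toggling). Appendages are found as the difference between the mask
#' and its morphological opening; each such connected region is dropped with
#' probability `severity`. Boundary pixels are then deleted with probability
#' `0.5 * severity`, and background pixels within `max_dilate_px` of the
#' foreground are added with probability `0.15 * severity`, so the
#' foreground never grows beyond that dilation bound.
#'
#' @param mask A 0/1 integer matrix.
#' @param severity Noise severity in `[0, 1]`; 0 returns the input exactly.
#' @param seed Integer seed.
#' @param max_dilate_px Dilation bound for boundary additions.
#' @return A 0/1 integer matrix of the same dimensions.
#' @export
perturb_mask <- function(mask, severity, seed = 1L, max_dilate_px = 1L) {
  mask <- as_binary_mask(mask)
  if (!is.numeric(severity) || length(severity) != 1L ||
      !is.finite(severity) || severity < 0 || severity > 1) {
    abort("`severity` must be a single value in [0, 1].")
  }
  if (is_empty_mask(mask)) abort("Cannot perturb an empty mask.")
  if (severity == 0) return(mask)
  with_seed(derive_seed(seed, "perturb"), {
    out <- mask
    # appendage dropout: opening removes structures thinner than the brush
    r <- ceiling(severity * 5)
    brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    opened <- as_binary_mask(EBImage::opening(out, brush))
    diff <- out - opened
    if (sum(diff) > 0) {
      lab <- label_components(diff)
      for (k in seq_len(max(lab))) {
        if (runif(1) < severity) out[lab == k] <- 0L
      }
    }
    if (sum(out) == 0L) out <- mask  # never delete the whole animal
    # boundary flicker
    pad <- function(m) {
      p <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
      p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
      p
    }
    nb4 <- function(m) {
      p <- pad(m)
      p[1:nrow(m), 2:(ncol(m) + 1L)] + p[3:(nrow(m) + 2L), 2:(ncol(m) + 1L)] +
        p[2:(nrow(m) + 1L), 1:ncol(m)] + p[2:(nrow(m) + 1L), 3:(ncol(m) + 2L)]
    }
    nb <- nb4(out)
    boundary <- which(out == 1L & nb < 4L)
    drop <- boundary[runif(length(boundary)) < 0.5 * severity]
    grown <- out
    for (i in seq_len(max_dilate_px)) {
      grown <- as_binary_mask(grown + nb4(grown))
    }
    halo <- which(out == 0L & grown == 1L)
    add <- halo[runif(length(halo)) < 0.15 * severity]
    out[drop] <- 0L
    out[add] <- 1L
    if (sum(out) == 0L) out <- mask
    out
  })
}

#' Generate a full synthetic capture dataset
#'
#' Samples a herd, then for each cow simulates `events_per_cow` capture
#' events. Each event draws a true stand-off distance uniformly from
#' `distance_range`; the *recorded* distance adds Gaussian LiDAR-style
#' jitter (`distance_noise_sd`). Each event yields a burst of
#' `images_per_event` silhouettes rendered at the true distance with
#' per-image pose jitter and segmentation noise of the given `severity`.
#'
#' @param n_cows,events_per_cow,images_per_event Positive integers; the
#'   default burst length is 5 consecutive images per event.
#' @param distance_range Stand-off distance range in metres (default the
#'   1.44-2.72 m working window).
#' @param distance_noise_sd SD (m) of the recorded-distance jitter.
#' @param severity Segmentation-noise severity passed to [perturb_mask()].
#' @param pose_jitter Pose variation severity passed to
#'   [render_silhouette()].
#' @param canvas,focal_px_m Raster geometry, see [render_silhouette()].
#' @param weight_mixture,girth_link Herd structure, see [sample_herd()].
#' @param seed Master integer seed; all stage seeds derive from it.
#' @return A list with class `"capture_dataset"`:
#'   * `captures`: tibble, one row per image (`cow_id`, `event_id`,
#'     `image_index`, `distance_m` — the recorded value — and `mask`, a
#'     list-column of 0/1 matrices);
#'   * `ground_truth`: tibble, one row per event (`event_id`, `cow_id`,
#'     `distance_m`, `true_distance_m`, `true_weight_kg`,
#'     `heart_girth_cm`);
#'   * `herd`: the sampled herd tibble.
#' @examples
#' ds <- generate_dataset(n_cows = 2, events_per_cow = 1, seed = 7)
#' nrow(ds$captures); nrow(ds$ground_truth)
#' @export
generate_dataset <- function(n_cows, events_per_cow = 1L,
                             images_per_event = 5L,
                             distance_range = c(1.44, 2.72),
                             distance_noise_sd = 0.01,
                             severity = 0.2,
                             pose_jitter = 0.05,
                             canvas = c(384L, 288L), focal_px_m = 240,
                             weight_mixture = default_weight_mixture(),
                             girth_link = default_girth_link(),
                             seed = 1L) {
  n_cows <- check_count(n_cows, "n_cows")
  events_per_cow <- check_count(events_per_cow, "events_per_cow")
  images_per_event <- check_count(images_per_event, "images_per_event")
  if (length(distance_range) != 2L || distance_range[1] > distance_range[2] ||
      distance_range[1] <= 0) {
    abort("`distance_range` must be c(lo, hi) with 0 < lo <= hi.")
  }
  if (distance_noise_sd < 0) abort("`distance_noise_sd` must be >= 0.")
  herd <- sample_herd(n_cows, weight_mixture, girth_link, seed = seed)
  rows <- vector("list", n_cows * events_per_cow)
  truth <- vector("list", n_cows * events_per_cow)
  k <- 0L
  for (i in seq_len(n_cows)) {
    cow <- herd[i, ]
    for (e in seq_len(events_per_cow)) {
      k <- k + 1L
      event_id <- sprintf("%s_e%02d", cow$cow_id, e)
      ev_seed <- derive_seed(seed, paste0("event_", event_id))
      dists <- with_seed(ev_seed, {
        d_true <- runif(1, distance_range[1], distance_range[2])
        d_rec <- max(d_true + rnorm(1, 0, distance_noise_sd), 0.1)
        c(d_true, d_rec)
      })
      masks <- vector("list", images_per_event)
      for (im in seq_len(images_per_event)) {
        im_seed <- derive_seed(seed, paste0("img_", event_id, "_", im))
        m <- render_silhouette(cow, dists[1], pose_jitter = pose_jitter,
                               canvas = canvas, focal_px_m = focal_px_m,
                               seed = im_seed)
        if (severity > 0) m <- perturb_mask(m, severity, seed = im_seed)
        masks[[im]] <- m
      }
      rows[[k]] <- tibble::tibble(
        cow_id = cow$cow_id, event_id = event_id,
        image_index = seq_len(images_per_event),
        distance_m = dists[2], mask = masks
      )
      truth[[k]] <- tibble::tibble(
        event_id = event_id, cow_id = cow$cow_id,
        distance_m = dists[2], true_distance_m = dists[1],
        true_weight_kg = cow$true_weight_kg,
        heart_girth_cm = cow$heart_girth_cm
      )
    }
  }
  structure(list(captures = dplyr::bind_rows(rows),
                 ground_truth = dplyr::bind_rows(truth),
                 herd = herd),
            class = "capture_dataset")
}

#' @export
print.capture_dataset <- function(x, ...) {
  cat(sprintf("<capture_dataset> %d cows, %d events, %d images\n",
              nrow(x$herd), nrow(x$ground_truth), nrow(x$captures)))
  invisible(x)
}

#' Write a capture dataset to disk
#'
#' Masks are written as 8-bit single-channel PNGs (0/255) named
#' `<event_id>_<image_index>.png`; metadata and ground truth go to
#' `captures.csv` (cow_id, event_id, image_index, distance_m, mask_file)
#' and `ground_truth.csv`.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_capture_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "capture_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(nrow(dataset$captures))
  for (i in seq_len(nrow(dataset$captures))) {
    f <- sprintf("%s_%02d.png", dataset$captures$event_id[i],
                 dataset$captures$image_index[i])
    write_mask_png(dataset$captures$mask[[i]], file.path(dir, f))
    files[i] <- f
  }
  meta <- dataset$captures |>
    dplyr::select(-"mask") |>
    dplyr::mutate(mask_file = files)
  utils::write.csv(meta, file.path(dir, "captures.csv"), row.names = FALSE)
  utils::write.csv(dataset$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
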