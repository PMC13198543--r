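# Brute-force oracles for the morphometric descriptors, written as plain
# double loops and textbook algorithms so they share no code path with the
# package implementation. Intended for small rasters (<= 64 x 64).

oracle_bbox <- function(mask) {
  rows <- integer(0); cols <- integer(0)
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c] == 1L) { rows <- c(rows, r); cols <- c(cols, c) }
  }
  c(width = max(cols) - min(cols) + 1, height = max(rows) - min(rows) + 1)
}

oracle_area <- function(mask) {
  a <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c] == 1L) a <- a + 1L
  }
  a
}

# crack perimeter by checking each pixel's 4 neighbours explicitly
oracle_perimeter <- function(mask) {
  p <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  at <- function(r, c) {
    if (r < 1 || r > nr || c < 1 || c > nc) 0L else mask[r, c]
  }
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c] == 1L) {
      p <- p + (at(r - 1, c) == 0L) + (at(r + 1, c) == 0L) +
        (at(r, c - 1) == 0L) + (at(r, c + 1) == 0L)
    }
  }
  p
}

# convex hull area by gift wrapping over ALL pixel corners
oracle_hull_area <- function(mask) {
  pts <- NULL
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c] == 1L) {
      pts <- rbind(pts, cbind(c(c - 1, c, c - 1, c), c(r - 1, r - 1, r, r)))
    }
  }
  pts <- unique(pts)
  if (nrow(pts) < 3L) return(0)
  # gift wrapping (Jarvis march)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- if (length(hull) == 1L) setdiff(seq_len(nrow(pts)), p) else
      seq_len(nrow(pts))[-p]
    q <- cand[1]
    for (r in cand[-1]) {
      cross <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
        (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      d_r <- sum((pts[r, ] - pts[p, ])^2)
      if (cross < 0 || (abs(cross) < 1e-12 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > nrow(pts)) stop("gift wrapping failed")
  }
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  n <- length(hull)
  abs(sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)) / 2
}

oracle_elongation <- function(mask) {
  xs <- numeric(0); ys <- numeric(0)
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c] == 1L) { xs <- c(xs, c - 0.5); ys <- c(ys, r - 0.5) }
  }
  n <- length(xs)
  mxx <- sum((xs - mean(xs))^2) / n + 1 / 12
  myy <- sum((ys - mean(ys))^2) / n + 1 / 12
  mxy <- sum((xs - mean(xs)) * (ys - mean(ys))) / n
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2, 2))$values
  sqrt(max(ev) / max(min(ev), .Machine$double.eps))
}

oracle_hu <- function(mask) {
  xs <- numeric(0); ys <- numeric(0)
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c] == 1L) { xs <- c(xs, c - 0.5); ys <- c(ys, r - 0.5) }
  }
  n <- length(xs)
  xb <- mean(xs); yb <- mean(ys)
  eta <- function(p, q) {
    sum((xs - xb)^p * (ys - yb)^q) / n^(1 + (p + q) / 2)
  }
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  c(n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2))
}

# small raster menagerie used by several oracle-equivalence tests
test_rasters <- function() {
  rect <- matrix(0L, 16, 28); rect[4:13, 5:24] <- 1L
  disc <- local({
    m <- matrix(0L, 33, 33)
    for (r in 1:33) for (c in 1:33) {
      if ((r - 17)^2 + (c - 17)^2 <= 14^2) m[r, c] <- 1L
    }
    m
  })
  plus <- local({
    m <- matrix(0L, 21, 21)
    m[9:13, 3:19] <- 1L
    m[3:19, 9:13] <- 1L
    m
  })
  lshape <- local({
    m <- matrix(0L, 20, 20)
    m[3:18, 3:7] <- 1L
    m[14:18, 3:18] <- 1L
    m
  })
  blobs <- lapply(1:4, function(s) {
    # connected by construction: random 4-neighbour walk from the centre
    set.seed(100 + s)
    m <- matrix(0L, 24, 24)
    r <- 12L; c <- 12L; m[r, c] <- 1L
    for (i in 1:250) {
      step <- sample(4, 1)
      r <- min(max(r + c(-1L, 1L, 0L, 0L)[step], 2L), 23L)
      c <- min(max(c + c(0L, 0L, -1L, 1L)[step], 2L), 23L)
      m[r, c] <- 1L
    }
    cowbands::clean_mask(m, min_component_area_px = 1L)
  })
  c(list(rect = rect, disc = disc, plus = plus, lshape = lshape), blobs)
}
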