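# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (Siddon traversal, vectorised TV, etc.).

# exact length of the intersection of ray (theta [rad], detector coord s)
# with one pixel (0-based row/col), by Liang-Barsky line/box clipping
oracle_ray_pixel_length <- function(theta, s, row, col, N) {
  u <- c(cos(theta), sin(theta))
  v <- c(-sin(theta), cos(theta))
  p0 <- s * u
  lo <- c(col - N / 2, row - N / 2)   # (x, y) lower corner
  hi <- lo + 1
  t0 <- -Inf; t1 <- Inf
  for (d in 1:2) {
    if (abs(v[d]) < 1e-14) {
      if (p0[d] <= lo[d] || p0[d] >= hi[d]) return(0)
    } else {
      ta <- (lo[d] - p0[d]) / v[d]
      tb <- (hi[d] - p0[d]) / v[d]
      t0 <- max(t0, min(ta, tb))
      t1 <- min(t1, max(ta, tb))
    }
  }
  max(0, t1 - t0)
}

# dense measurement matrix (M x N^2, column-major pixels, rows in
# angle-major ray order) built pixel by pixel from the clipping oracle
oracle_radon_matrix <- function(angles_deg, N, n_bins = N) {
  th <- angles_deg * pi / 180
  cdet <- (n_bins - 1) / 2
  M <- length(th) * n_bins
  Phi <- matrix(0, M, N * N)
  for (a in seq_along(th)) for (b in seq_len(n_bins)) {
    r <- (a - 1) * n_bins + b
    for (col in 0:(N - 1)) for (row in 0:(N - 1)) {
      len <- oracle_ray_pixel_length(th[a], (b - 1) - cdet, row, col, N)
      if (len > 0) Phi[r, row + 1 + N * col] <- len
    }
  }
  Phi
}

# explicit double-loop evaluation of the TV sum (and gradient magnitude)
oracle_tv <- function(p) {
  N <- nrow(p); M <- ncol(p)
  acc <- 0
  for (t1 in 1:(N - 1)) for (t2 in 1:(M - 1))
    acc <- acc + sqrt((p[t1 + 1, t2] - p[t1, t2])^2 +
                        (p[t1, t2 + 1] - p[t1, t2])^2)
  acc
}

oracle_gradient_magnitude <- function(p) {
  N <- nrow(p); M <- ncol(p)
  q <- matrix(0, N - 1, M - 1)
  for (t1 in 1:(N - 1)) for (t2 in 1:(M - 1))
    q[t1, t2] <- sqrt((p[t1 + 1, t2] - p[t1, t2])^2 +
                        (p[t1, t2 + 1] - p[t1, t2])^2)
  q
}

# explicit loop over mask pixels for the AP/MP statistics
oracle_ap_mp <- function(f1, f2, mask) {
  vals <- c()
  for (i in seq_len(nrow(f1))) for (j in seq_len(ncol(f1)))
    if (mask[i, j]) vals <- c(vals, abs(f1[i, j] - f2[i, j]))
  c(ap = mean(vals), mp = max(vals))
}

# smoothed TV functional matching tv_descent_direction's definition
oracle_smoothed_tv <- function(p, eps) {
  N <- nrow(p); M <- ncol(p)
  acc <- 0
  for (t1 in 1:(N - 1)) for (t2 in 1:(M - 1))
    acc <- acc + sqrt((p[t1 + 1, t2] - p[t1, t2])^2 +
                        (p[t1, t2 + 1] - p[t1, t2])^2 + eps^2)
  acc
}

# central-difference numeric gradient of the smoothed TV
oracle_numeric_tv_gradient <- function(p, eps, h = 1e-6) {
  g <- matrix(0, nrow(p), ncol(p))
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    p1 <- p; p1[i, j] <- p1[i, j] + h
    p2 <- p; p2[i, j] <- p2[i, j] - h
    g[i, j] <- (oracle_smoothed_tv(p1, eps) - oracle_smoothed_tv(p2, eps)) /
      (2 * h)
  }
  g
}

# brute-force nearest-neighbour matching with the Lowe ratio test
oracle_match_count <- function(d1, d2, ratio) {
  n <- 0L
  for (i in seq_len(nrow(d1))) {
    dist <- sqrt(rowSums(sweep(d2, 2, d1[i, ])^2))
    o <- order(dist)
    if (length(dist) >= 2 && dist[o[1]] < ratio * dist[o[2]]) n <- n + 1L
  }
  n
}

# minimal single-page 8-bit RGB TIFF writer (independent of the package's
# float writer), used to test the reader's RGB-to-gray path
write_rgb_tiff <- function(r, g, b, path) {
  height <- nrow(r); width <- ncol(r)
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(as.integer(x), con, size = size,
                                  endian = "little")
  nbytes <- width * height * 3
  writeChar("II", con, eos = NULL); w(42, 2); w(8 + nbytes, 4)
  # interleaved RGB rows
  px <- integer(nbytes)
  k <- 1
  for (i in seq_len(height)) for (j in seq_len(width)) {
    px[k:(k + 2)] <- c(r[i, j], g[i, j], b[i, j]); k <- k + 3
  }
  writeBin(as.raw(px), con)
  tags <- list(c(256, 4, 1, width), c(257, 4, 1, height),
               c(258, 3, 1, 8), c(259, 3, 1, 1), c(262, 3, 1, 2),
               c(273, 4, 1, 8), c(277, 3, 1, 3), c(278, 4, 1, height),
               c(279, 4, 1, nbytes))
  w(length(tags), 2)
  for (tg in tags) { w(tg[1], 2); w(tg[2], 2); w(tg[3], 4); w(tg[4], 4) }
  w(0, 4)
  invisible(path)
}

# small deterministic acquisition shared by gating/alignment tests
small_acquisition <- function(n_angles = 8, amplitude = 0.04, period = 10,
                              jitter = FALSE, seed = 7, ...) {
  geom <- acquisition_geometry(n_angles = n_angles, angle_step = 3,
                               frames_per_angle = 20)
  make_breathing_phantom(N = 64, geometry = geom, period = period,
                         amplitude = amplitude, jitter = jitter,
                         seed = seed, ...)
}
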