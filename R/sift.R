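# Scale-space keypoint detection (Gaussian/DoG pyramid), SIFT-style
# gradient-orientation-histogram descriptors, and exhaustive
# nearest-neighbour matching with the Lowe ratio test.

# local 3x3 max/min excluding the centre pixel, -Inf/-+Inf padded borders
neigh8 <- function(M, op) {
  nr <- nrow(M); nc <- ncol(M)
  pad <- if (identical(op, pmax)) -Inf else Inf
  P <- matrix(pad, nr + 2, nc + 2)
  P[2:(nr + 1), 2:(nc + 1)] <- M
  out <- matrix(pad, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- op(out, P[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)])
  }
  out
}

# 3x3 max/min including the centre
neigh9 <- function(M, op) op(neigh8(M, op), M)

# Gaussian + DoG pyramid for one octave; returns gaussian levels, their
# absolute sigmas and the DoG stack
build_octave <- function(base, sigma_base, sigma0, s) {
  sig <- sigma0 * 2^((0:(s + 2)) / s)
  gs <- vector("list", s + 3)
  cur <- if (sig[1] > sigma_base)
    cpp_gauss_blur(base, sqrt(sig[1]^2 - sigma_base^2)) else base
  gs[[1]] <- cur
  for (i in 2:(s + 3)) {
    cur <- cpp_gauss_blur(cur, sqrt(sig[i]^2 - sig[i - 1]^2))
    gs[[i]] <- cur
  }
  dog <- lapply(seq_len(s + 2), function(i) gs[[i + 1]] - gs[[i]])
  list(gauss = gs, dog = dog, sigmas = sig)
}

# dominant gradient orientations (radians) at one keypoint from a 36-bin
# magnitude-weighted histogram; peaks within 80% of the maximum (max 2)
keypoint_orientations <- function(gx, gy, row, col, sigma) {
  nr <- nrow(gx); nc <- ncol(gx)
  r <- max(3L, round(2.5 * 1.5 * sigma))
  rows <- max(1L, row - r):min(nr, row + r)
  cols <- max(1L, col - r):min(nc, col + r)
  sgx <- gx[rows, cols]; sgy <- gy[rows, cols]
  mag <- sqrt(sgx^2 + sgy^2)
  w <- exp(-(outer((rows - row)^2, (cols - col)^2, `+`)) /
             (2 * (1.5 * sigma)^2))
  ang <- atan2(sgy, sgx)
  bins <- (floor((ang + pi) / (2 * pi) * 36) %% 36) + 1
  h <- vapply(1:36, function(b) sum((mag * w)[bins == b]), numeric(1))
  if (max(h) <= 0) return(0)
  pk <- which(h >= 0.8 * max(h))
  pk <- pk[order(h[pk], decreasing = TRUE)][seq_len(min(2, length(pk)))]
  (pk - 0.5) / 36 * 2 * pi - pi
}

#' Detect scale-space keypoints
#'
#' Gaussian-pyramid difference-of-Gaussians (DoG) keypoint detector: the
#' image is repeatedly smoothed and downsampled, adjacent smoothing levels
#' are subtracted, and keypoints are the strict local extrema of the DoG
#' stack over space and scale. Low-contrast extrema and edge responses
#' (principal-curvature ratio of the 2x2 DoG Hessian above
#' `edge_ratio_threshold`) are rejected. Each keypoint is assigned one or
#' two dominant gradient orientations.
#'
#' @param image Grayscale matrix, at least 32 x 32 (internally normalised
#'   to `[0, 1]`).
#' @param octaves Number of pyramid octaves (default 3; capped so the
#'   coarsest level stays at least 16 pixels wide).
#' @param scales_per_octave DoG levels per octave that are searched for
#'   extrema (default 3, i.e. adjacent-level scale ratio `2^(1/3)`; use 1
#'   for an exact per-level ratio of 2).
#' @param edge_ratio_threshold Principal-curvature ratio above which an
#'   extremum is discarded as an edge response (default 10).
#' @param contrast_threshold Minimum |DoG| value of a keypoint, on the
#'   normalised intensity scale (default 0.015).
#' @param sigma0 Base smoothing scale of each octave (default 1.6 px).
#' @return Data frame with columns `x`, `y` (0-based pixel coordinates in
#'   the input image), `scale` (px), `orientation` (radians), `response`,
#'   `octave`, `level`.
#' @export
detect_keypoints <- function(image, octaves = 3, scales_per_octave = 3,
                             edge_ratio_threshold = 10,
                             contrast_threshold = 0.015, sigma0 = 1.6) {
  image <- as.matrix(image)
  if (min(dim(image)) < 32) stop("image must be at least 32 x 32")
  rng <- max(image) - min(image)
  empty <- data.frame(x = numeric(0), y = numeric(0), scale = numeric(0),
                      orientation = numeric(0), response = numeric(0),
                      octave = integer(0), level = integer(0))
  if (rng == 0) return(empty)
  img <- (image - min(image)) / rng
  s <- scales_per_octave
  max_oct <- max(1L, floor(log2(min(dim(img)) / 16)) + 1L)
  octaves <- min(octaves, max_oct)
  er <- (edge_ratio_threshold + 1)^2 / edge_ratio_threshold

  out <- empty
  base <- img; sigma_base <- 0.5
  for (o in seq_len(octaves)) {
    oc <- build_octave(base, sigma_base, sigma0, s)
    grads <- lapply(oc$gauss, function(g) {
      nr <- nrow(g); nc <- ncol(g)
      gx <- (cbind(g[, -1], g[, nc]) - cbind(g[, 1], g[, -nc])) / 2
      gy <- (rbind(g[-1, ], g[nr, ]) - rbind(g[1, ], g[-nr, ])) / 2
      list(gx = gx, gy = gy)
    })
    for (lev in 2:(s + 1)) {
      D <- oc$dog[[lev]]
      hi <- pmax(neigh8(D, pmax),
                 neigh9(oc$dog[[lev - 1]], pmax),
                 neigh9(oc$dog[[lev + 1]], pmax))
      lo <- pmin(neigh8(D, pmin),
                 neigh9(oc$dog[[lev - 1]], pmin),
                 neigh9(oc$dog[[lev + 1]], pmin))
      ext <- (D > hi | D < lo) & abs(D) > contrast_threshold
      ext[c(1, nrow(D)), ] <- FALSE
      ext[, c(1, ncol(D))] <- FALSE
      idx <- which(ext, arr.ind = TRUE)
      if (!nrow(idx)) next
      keep <- logical(nrow(idx))
      for (k in seq_len(nrow(idx))) {
        i <- idx[k, 1]; j <- idx[k, 2]
        dxx <- D[i, j + 1] + D[i, j - 1] - 2 * D[i, j]
        dyy <- D[i + 1, j] + D[i - 1, j] - 2 * D[i, j]
        dxy <- (D[i + 1, j + 1] + D[i - 1, j - 1] -
                  D[i + 1, j - 1] - D[i - 1, j + 1]) / 4
        det <- dxx * dyy - dxy^2
        keep[k] <- det > 0 && (dxx + dyy)^2 / det < er
      }
      idx <- idx[keep, , drop = FALSE]
      if (!nrow(idx)) next
      g <- grads[[lev]]
      for (k in seq_len(nrow(idx))) {
        i <- idx[k, 1]; j <- idx[k, 2]
        # sub-pixel spatial refinement: quadratic fit of the DoG surface
        gx1 <- (D[i, j + 1] - D[i, j - 1]) / 2
        gy1 <- (D[i + 1, j] - D[i - 1, j]) / 2
        dxx <- D[i, j + 1] + D[i, j - 1] - 2 * D[i, j]
        dyy <- D[i + 1, j] + D[i - 1, j] - 2 * D[i, j]
        dxy <- (D[i + 1, j + 1] + D[i - 1, j - 1] -
                  D[i + 1, j - 1] - D[i - 1, j + 1]) / 4
        det <- dxx * dyy - dxy^2
        off <- if (abs(det) > 1e-12) {
          c(-(dyy * gx1 - dxy * gy1), -(dxx * gy1 - dxy * gx1)) / det
        } else c(0, 0)
        off <- pmin(pmax(off, -0.5), 0.5)
        oris <- keypoint_orientations(g$gx, g$gy, i, j, oc$sigmas[lev])
        for (ori in oris)
          out <- rbind(out, data.frame(
            x = (j - 1 + off[1]) * 2^(o - 1), y = (i - 1 + off[2]) * 2^(o - 1),
            scale = oc$sigmas[lev] * 2^(o - 1), orientation = ori,
            response = D[i, j], octave = o, level = lev))
      }
    }
    nxt <- oc$gauss[[s + 1]]
    base <- nxt[seq(1, nrow(nxt), 2), seq(1, ncol(nxt), 2)]
    sigma_base <- sigma0
    if (min(dim(base)) < 16) break
  }
  rownames(out) <- NULL
  out
}

#' SIFT-style descriptors for keypoints
#'
#' Builds the standard 4x4-cell, 8-orientation-bin gradient histogram
#' descriptor (128 values) around each keypoint: a 16x16 sample grid scaled
#' by the keypoint scale and rotated by its orientation, Gaussian-weighted
#' gradient magnitudes accumulated with bilinear spatial interpolation,
#' normalised to unit length, clipped at 0.2 and renormalised (so the
#' descriptor is invariant to affine intensity gain).
#'
#' @param image Grayscale matrix (same one given to [detect_keypoints()]).
#' @param keypoints Data frame from [detect_keypoints()].
#' @param spacing_factor Sample spacing in units of the keypoint scale
#'   (default 0.75, a 12-sigma descriptor footprint).
#' @return List with `keypoints` (rows that yielded a descriptor; keypoints
#'   within 1 px of the border are dropped with a message) and
#'   `descriptors` (matrix, one unit-norm row of length 128 per keypoint).
#' @export
describe_keypoints <- function(image, keypoints, spacing_factor = 0.75) {
  image <- as.matrix(image)
  rng <- max(image) - min(image)
  img <- if (rng > 0) (image - min(image)) / rng else image * 0
  nr <- nrow(img); nc <- ncol(img)
  if (nrow(keypoints) == 0)
    return(list(keypoints = keypoints,
                descriptors = matrix(0, 0, 128)))
  inside <- keypoints$x >= 1 & keypoints$x <= nc - 2 &
    keypoints$y >= 1 & keypoints$y <= nr - 2
  if (any(!inside))
    message(sprintf("dropped %d keypoint(s) too close to the border",
                    sum(!inside)))
  keypoints <- keypoints[inside, , drop = FALSE]
  if (nrow(keypoints) == 0)
    return(list(keypoints = keypoints, descriptors = matrix(0, 0, 128)))

  # gradient fields cached per distinct smoothing scale
  grad_cache <- new.env(parent = emptyenv())
  grad_at <- function(sigma) {
    key <- sprintf("s%.2f", sigma)
    if (!is.null(grad_cache[[key]])) return(grad_cache[[key]])
    g <- cpp_gauss_blur(img, max(sigma / 2, 0.5))
    gx <- (cbind(g[, -1], g[, nc]) - cbind(g[, 1], g[, -nc])) / 2
    gy <- (rbind(g[-1, ], g[nr, ]) - rbind(g[1, ], g[-nr, ])) / 2
    grad_cache[[key]] <- list(gx = gx, gy = gy)
    grad_cache[[key]]
  }

  grid <- expand.grid(u = seq(-7.5, 7.5, by = 1), v = seq(-7.5, 7.5, by = 1))
  wspat <- exp(-(grid$u^2 + grid$v^2) / (2 * 6^2))
  desc <- matrix(0, nrow(keypoints), 128)
  for (k in seq_len(nrow(keypoints))) {
    kp <- keypoints[k, ]
    g <- grad_at(kp$scale)
    h <- spacing_factor * kp$scale
    ct <- cos(kp$orientation); st <- sin(kp$orientation)
    px <- kp$x + (grid$u * ct - grid$v * st) * h
    py <- kp$y + (grid$u * st + grid$v * ct) * h
    sgx <- cpp_bilinear_sample(g$gx, matrix(px, ncol = 1),
                               matrix(py, ncol = 1))
    sgy <- cpp_bilinear_sample(g$gy, matrix(px, ncol = 1),
                               matrix(py, ncol = 1))
    mag <- sqrt(sgx^2 + sgy^2) * wspat
    ang <- atan2(sgy, sgx) - kp$orientation
    ob <- (round(ang / (2 * pi / 8)) %% 8) + 1
    cu <- (grid$u + 8) / 4 - 0.5
    cv <- (grid$v + 8) / 4 - 0.5
    c0u <- floor(cu); wu <- cu - c0u
    c0v <- floor(cv); wv <- cv - c0v
    d <- numeric(128)
    for (du in 0:1) for (dv in 0:1) {
      cuu <- c0u + du; cvv <- c0v + dv
      ok <- cuu >= 0 & cuu <= 3 & cvv >= 0 & cvv <= 3
      if (!any(ok)) next
      wgt <- (if (du == 1) wu else 1 - wu) * (if (dv == 1) wv else 1 - wv)
      bin <- (cvv * 4 + cuu) * 8 + ob   # 1..128
      contrib <- mag * wgt
      for (q in which(ok & contrib > 0))
        d[bin[q]] <- d[bin[q]] + contrib[q]
    }
    nn <- sqrt(sum(d^2))
    if (nn > 0) {
      d <- pmin(d / nn, 0.2)
      d <- d / sqrt(sum(d^2))
    }
    desc[k, ] <- d
  }
  ok <- rowSums(desc^2) > 0
  list(keypoints = keypoints[ok, , drop = FALSE],
       descriptors = desc[ok, , drop = FALSE])
}

#' Exhaustive nearest-neighbour descriptor matching
#'
#' Brute-force nearest neighbour in descriptor space with the Lowe ratio
#' test: a keypoint of set 1 is matched to its nearest neighbour in set 2
#' when the nearest distance is below `ratio_threshold` times the
#' second-nearest. With a single candidate in set 2 the ratio test is
#' inapplicable and an absolute-distance fallback is used.
#'
#' @param desc1,desc2 Descriptor matrices (rows are unit-norm descriptors).
#' @param ratio_threshold Lowe ratio (default 0.8).
#' @param abs_threshold Absolute-distance fallback threshold when set 2 has
#'   a single descriptor (default 0.7).
#' @return Data frame with columns `i`, `j`, `dist` (possibly 0 rows).
#' @export
match_nn <- function(desc1, desc2, ratio_threshold = 0.8,
                     abs_threshold = 0.7) {
  empty <- data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  if (is.null(desc1) || is.null(desc2) ||
      nrow(desc1) == 0 || nrow(desc2) == 0) return(empty)
  d2 <- pmax(outer(rowSums(desc1^2), rowSums(desc2^2), `+`) -
               2 * tcrossprod(desc1, desc2), 0)
  res <- lapply(seq_len(nrow(desc1)), function(i) {
    d <- sqrt(d2[i, ])
    if (length(d) == 1) {
      if (d[1] <= abs_threshold)
        return(data.frame(i = i, j = 1L, dist = d[1]))
      return(NULL)
    }
    o <- order(d)[1:2]
    if (d[o[1]] < ratio_threshold * d[o[2]])
      return(data.frame(i = i, j = o[1], dist = d[o[1]]))
    NULL
  })
  res <- do.call(rbind, res)
  if (is.null(res)) empty else res
}
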