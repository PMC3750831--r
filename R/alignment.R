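# 4-DOF similarity transforms, robust estimation with RANSAC, image
# resampling, and chained alignment of a per-angle projection sequence.

#' 4-DOF similarity transform
#'
#' The planar mapping `x' = s R(theta) x + t` with isotropic scale `s`,
#' rotation `theta` and translation `t`: four degrees of freedom, shape
#' preserving. Stored with its 3x3 homogeneous matrix `H`.
#'
#' @param s Scale (> 0).
#' @param theta Rotation in radians.
#' @param t Translation, length-2 (pixels).
#' @return Object of class `similarity_transform`.
#' @export
similarity_transform <- function(s = 1, theta = 0, t = c(0, 0)) {
  s <- unname(s); theta <- unname(theta); t <- unname(as.numeric(t))
  if (s <= 0) stop("scale must be positive")
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  H <- rbind(cbind(s * R, t), c(0, 0, 1))
  dimnames(H) <- NULL
  structure(list(s = s, theta = theta, t = t, H = H),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "similarity transform: s = %.6g, theta = %.6g deg, t = (%.4g, %.4g)\n",
    x$s, x$theta * 180 / pi, x$t[1], x$t[2]))
  invisible(x)
}

#' Compose two similarity transforms
#'
#' Returns the transform applying `b` first, then `a`; scales multiply and
#' rotations add.
#' @param a,b [similarity_transform()] objects.
#' @return A [similarity_transform()].
#' @export
compose_transforms <- function(a, b) {
  H <- a$H %*% b$H
  similarity_transform(a$s * b$s,
                       atan2(H[2, 1], H[1, 1]),
                       H[1:2, 3])
}

#' Invert a similarity transform
#' @param tf A [similarity_transform()].
#' @return The inverse [similarity_transform()].
#' @export
invert_transform <- function(tf) {
  Rinv <- t(matrix(c(cos(tf$theta), sin(tf$theta),
                     -sin(tf$theta), cos(tf$theta)), 2, 2)) / tf$s
  similarity_transform(1 / tf$s, -tf$theta, -as.numeric(Rinv %*% tf$t))
}

#' Apply a similarity transform to points
#' @param tf A [similarity_transform()].
#' @param pts `n x 2` matrix of (x, y) coordinates.
#' @return `n x 2` matrix of mapped coordinates.
#' @export
transform_points <- function(tf, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  sweep(pts %*% t(tf$H[1:2, 1:2]), 2, tf$H[1:2, 3], `+`)
}

#' Resample an image under a similarity transform
#'
#' Produces the image whose content has been moved by `transform`: output
#' pixel `x'` takes the bilinear interpolation of the input at
#' `H^{-1} x'`. Pixels mapping outside the field of view are filled with
#' `fill`.
#'
#' @param image Grayscale matrix.
#' @param transform A [similarity_transform()].
#' @param fill Out-of-field value (default 0).
#' @return Matrix of the same shape.
#' @export
warp <- function(image, transform, fill = 0) {
  N <- nrow(image); M <- ncol(image)
  inv <- invert_transform(transform)
  xg <- matrix(0:(M - 1), N, M, byrow = TRUE)
  yg <- matrix(0:(N - 1), N, M)
  xs <- inv$H[1, 1] * xg + inv$H[1, 2] * yg + inv$H[1, 3]
  ys <- inv$H[2, 1] * xg + inv$H[2, 2] * yg + inv$H[2, 3]
  if (fill == 0) return(cpp_bilinear_sample(image, xs, ys))
  fill + cpp_bilinear_sample(image - fill, xs, ys)
}

# closed-form similarity from point pairs via complex least squares:
# z2 = a z1 + b with a = s exp(i theta)
fit_similarity_ls <- function(p1, p2) {
  z1 <- complex(real = p1[, 1], imaginary = p1[, 2])
  z2 <- complex(real = p2[, 1], imaginary = p2[, 2])
  m1 <- mean(z1); m2 <- mean(z2)
  den <- sum(Mod(z1 - m1)^2)
  if (den < 1e-12) return(NULL)
  a <- sum((z2 - m2) * Conj(z1 - m1)) / den
  if (Mod(a) < 1e-12) return(NULL)
  b <- m2 - a * m1
  similarity_transform(Mod(a), Arg(a), c(Re(b), Im(b)))
}

#' RANSAC estimation of a similarity transform from matched points
#'
#' Repeatedly fits the 2-point closed-form similarity on random minimal
#' samples, keeps the consensus-maximal model, and re-fits it by least
#' squares on all inliers (twice, with inliers recomputed in between).
#'
#' @param matches Optional match table (data frame with columns `i`, `j`
#'   indexing `points1`/`points2`); `NULL` when the rows of the two point
#'   sets already correspond.
#' @param points1,points2 `n x 2` coordinate matrices.
#' @param inlier_px Inlier residual threshold in pixels (default 2).
#' @param max_trials Maximum RANSAC trials (default 2000; adaptive early
#'   exit at 99.9% confidence).
#' @param seed Optional RNG seed, for run-to-run reproducibility.
#' @param min_inliers Consensus floor (default 4); below it estimation
#'   fails.
#' @param theta_bound Reject candidate models rotating by more than this
#'   (radians, default `Inf`); a domain prior for sequences known to be
#'   nearly aligned.
#' @param scale_bounds Length-2 admissible scale range (default
#'   `c(0, Inf)`).
#' @return List with `transform` ([similarity_transform()]), `inliers`
#'   (logical), `n_inliers`, `residuals` (pixels, for all pairs).
#' @export
ransac_similarity <- function(matches = NULL, points1, points2,
                              inlier_px = 2, max_trials = 2000, seed = NULL,
                              min_inliers = 4, theta_bound = Inf,
                              scale_bounds = c(0, Inf)) {
  if (!is.null(matches)) {
    points1 <- points1[matches$i, , drop = FALSE]
    points2 <- points2[matches$j, , drop = FALSE]
  }
  p1 <- matrix(as.numeric(points1), ncol = 2)
  p2 <- matrix(as.numeric(points2), ncol = 2)
  n <- nrow(p1)
  if (n < 2) stop("at least 2 matches are required to estimate a similarity")
  z1 <- complex(real = p1[, 1], imaginary = p1[, 2])
  z2 <- complex(real = p2[, 1], imaginary = p2[, 2])

  run <- function() {
    best_inl <- NULL; best_n <- 0L
    trials_needed <- max_trials
    trial <- 0L
    while (trial < min(max_trials, trials_needed)) {
      trial <- trial + 1L
      id <- sample.int(n, 2L)
      dz <- z1[id[1]] - z1[id[2]]
      if (Mod(dz) < 1e-9) next
      a <- (z2[id[1]] - z2[id[2]]) / dz
      if (Mod(a) < 1e-12) next
      if (Mod(a) < scale_bounds[1] || Mod(a) > scale_bounds[2] ||
          abs(Arg(a)) > theta_bound) next
      b <- z2[id[1]] - a * z1[id[1]]
      resid <- Mod(a * z1 + b - z2)
      inl <- resid <= inlier_px
      ninl <- sum(inl)
      if (ninl > best_n) {
        best_n <- ninl; best_inl <- inl
        w <- max(ninl / n, .Machine$double.eps)
        trials_needed <- ceiling(log(1e-3) / log(max(1 - w^2, 1e-12)))
      }
      if (best_n == n) break
    }
    best_inl
  }
  inl <- if (is.null(seed)) run() else with_seed(seed, run())
  if (is.null(inl) || sum(inl) < max(2L, min_inliers))
    stop(sprintf(
      "alignment failure: consensus of %d inlier(s) is below the floor %d",
      if (is.null(inl)) 0L else sum(inl), min_inliers))

  for (pass in 1:2) {
    tf <- fit_similarity_ls(p1[inl, , drop = FALSE], p2[inl, , drop = FALSE])
    if (is.null(tf)) stop("alignment failure: degenerate inlier set")
    resid <- Mod(complex(real = tf$H[1, 1] * p1[, 1] + tf$H[1, 2] * p1[, 2] +
                           tf$H[1, 3] - p2[, 1],
                         imaginary = tf$H[2, 1] * p1[, 1] +
                           tf$H[2, 2] * p1[, 2] + tf$H[2, 3] - p2[, 2]))
    inl <- resid <= inlier_px
    if (sum(inl) < max(2L, min_inliers))
      stop("alignment failure: inlier set collapsed during refit")
  }
  list(transform = tf, inliers = inl, n_inliers = sum(inl),
       residuals = resid)
}

#' Align a per-angle frame sequence to a common reference
#'
#' Estimates pairwise similarity transforms between frames separated by
#' `chain_step` (keypoint detection, SIFT-style description, exhaustive
#' nearest-neighbour matching, RANSAC), then composes them so every frame
#' maps into the coordinates of the first. A pair whose estimation fails
#' falls back to the identity link with a warning and is reported in the
#' result.
#'
#' @param frames List of grayscale matrices (or `N x M x F` array), one
#'   frame per angle.
#' @param chain_step Angular step between matched frames (default 1).
#' @param ratio_threshold Lowe ratio for [match_nn()] (default 0.8).
#' @param inlier_px,max_trials,min_inliers RANSAC settings, see
#'   [ransac_similarity()].
#' @param theta_bound,scale_bounds Admissible pairwise model range
#'   (defaults: 15 degrees, scale in `[0.8, 1.25]`); consecutive views of
#'   a nearly aligned sequence cannot jump further than this.
#' @param drift_correction Chaining pairwise estimates accumulates a
#'   random-walk drift (each link's small error compounds), while the true
#'   per-angle perturbation of a stationary subject is bounded and
#'   uncorrelated across angles. `"detrend"` removes a running-mean trend
#'   (window `drift_window`) from the cumulative transform parameters;
#'   `"none"` (default) keeps the raw pairwise chain.
#' @param drift_window Running-mean window in angles (default 15).
#' @param seed RNG seed for RANSAC (default 1).
#' @param contrast_threshold Keypoint contrast threshold (default 0.008;
#'   edge-enhanced projections are low-contrast).
#' @param ... Passed to [detect_keypoints()].
#' @return List with `transforms` (per frame, cumulative
#'   [similarity_transform()] to frame 1), `n_inliers`, `n_keypoints`,
#'   `failed_pairs` (integer indices `i` of failed links `i -> i - step`).
#' @export
align_sequence <- function(frames, chain_step = 1, ratio_threshold = 0.8,
                           inlier_px = 2, max_trials = 2000,
                           min_inliers = 4, theta_bound = 15 * pi / 180,
                           scale_bounds = c(0.8, 1.25),
                           drift_correction = c("none", "detrend"),
                           drift_window = 15, seed = 1,
                           contrast_threshold = 0.008, ...) {
  drift_correction <- match.arg(drift_correction)
  if (!is.list(frames)) {
    frames <- as_frame_array(frames)
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  }
  n <- length(frames)
  if (n < 2) stop("need at least 2 frames")
  feats <- lapply(frames, function(fr) {
    kp <- detect_keypoints(fr, contrast_threshold = contrast_threshold, ...)
    describe_keypoints(fr, kp)
  })
  transforms <- vector("list", n)
  transforms[[1]] <- similarity_transform()
  n_inliers <- integer(n)
  failed <- integer(0)
  last_aligned <- 1L
  for (i in seq(1L + chain_step, n, by = chain_step)) {
    prev <- i - chain_step
    link <- tryCatch({
      f1 <- feats[[i]]; f0 <- feats[[prev]]
      if (nrow(f1$keypoints) == 0 || nrow(f0$keypoints) == 0)
        stop("no keypoints")
      m <- match_nn(f1$descriptors, f0$descriptors, ratio_threshold)
      if (nrow(m) < 2) stop("too few matches")
      ransac_similarity(m,
                        as.matrix(f1$keypoints[, c("x", "y")]),
                        as.matrix(f0$keypoints[, c("x", "y")]),
                        inlier_px = inlier_px, max_trials = max_trials,
                        seed = seed + i, min_inliers = min_inliers,
                        theta_bound = theta_bound,
                        scale_bounds = scale_bounds)
    }, error = function(e) e)
    if (inherits(link, "error")) {
      warning(sprintf("pair %d -> %d failed (%s); using identity link",
                      i, prev, conditionMessage(link)))
      failed <- c(failed, i)
      transforms[[i]] <- transforms[[prev]]
    } else {
      transforms[[i]] <- compose_transforms(transforms[[prev]],
                                            link$transform)
      n_inliers[i] <- link$n_inliers
    }
    last_aligned <- i
  }
  # frames skipped by chain_step > 1 inherit the nearest aligned transform
  for (i in seq_len(n))
    if (is.null(transforms[[i]]))
      transforms[[i]] <- transforms[[max(1L, i - (i - 1L) %% chain_step)]]
  if (drift_correction == "detrend")
    transforms <- detrend_transforms(transforms, drift_window)
  list(transforms = transforms, n_inliers = n_inliers,
       n_keypoints = vapply(feats, function(f) nrow(f$keypoints),
                            integer(1)),
       failed_pairs = failed)
}

# remove the running-mean trend of the cumulative transform parameters,
# leaving the angle-local (jitter-correcting) component
detrend_transforms <- function(transforms, window = 15) {
  n <- length(transforms)
  p <- vapply(transforms, function(tf) c(tf$t, tf$theta, log(tf$s)),
              numeric(4))
  half <- max(1L, window %/% 2)
  run_mean <- function(v) vapply(seq_len(n), function(i)
    mean(v[max(1, i - half):min(n, i + half)]), numeric(1))
  trend <- t(apply(p, 1, run_mean))
  lapply(seq_len(n), function(a) {
    q <- similarity_transform(exp(trend[4, a]), trend[3, a], trend[1:2, a])
    compose_transforms(invert_transform(q), transforms[[a]])
  })
}
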