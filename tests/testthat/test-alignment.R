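# Similarity transforms, keypoints, descriptors, matching, RANSAC and
# chained sequence alignment.

test_that("similarity transforms form a group with 4 degrees of freedom", {
  a <- similarity_transform(1.2, 0.3, c(2, -1))
  b <- similarity_transform(0.8, -0.1, c(-3, 4))
  ab <- compose_transforms(a, b)
  expect_equal(ab$s, 1.2 * 0.8, tolerance = 1e-9)
  expect_equal(ab$theta, 0.2, tolerance = 1e-9)
  # H applied to homogeneous points reproduces s R x + t
  pts <- matrix(c(1, 2, -3, 0.5), 2, 2)
  R <- matrix(c(cos(0.3), sin(0.3), -sin(0.3), cos(0.3)), 2, 2)
  expect_equal(transform_points(a, pts),
               t(1.2 * R %*% t(pts) + c(2, -1)), tolerance = 1e-12)
  # rotation block is orthogonal with determinant 1 (up to scale)
  A <- a$H[1:2, 1:2] / a$s
  expect_equal(t(A) %*% A, diag(2), tolerance = 1e-12)
  expect_equal(det(A), 1, tolerance = 1e-12)

  inv <- compose_transforms(a, invert_transform(a))
  expect_equal(inv$s, 1, tolerance = 1e-12)
  expect_equal(inv$t, c(0, 0), tolerance = 1e-12)
  expect_error(similarity_transform(s = -1), "positive")
})

test_that("warp: identity, integer shifts, and inverse round trips", {
  img <- chest_phantom(64)
  expect_equal(warp(img, similarity_transform()), img, tolerance = 1e-12)

  sh <- warp(img, similarity_transform(t = c(3, -2)))
  expect_equal(sh[1:60, 4:64], img[3:62, 1:61], tolerance = 1e-12)

  # round trip on a smooth image: interpolation error under 1% of range
  smooth <- tomogate:::cpp_gauss_blur(matrix(runif(64 * 64), 64), 2)
  tf <- similarity_transform(1.03, 2 * pi / 180, c(1.5, -2.2))
  rt <- warp(warp(smooth, tf), invert_transform(tf))
  interior <- 10:54
  rng <- max(smooth) - min(smooth)
  expect_lt(mean(abs((rt - smooth)[interior, interior])), 0.01 * rng)
})

test_that("keypoint detector finds blobs, rejects edges and flat images", {
  expect_equal(nrow(detect_keypoints(matrix(5, 64, 64))), 0)

  N <- 64
  xg <- matrix(0:(N - 1), N, N, byrow = TRUE)
  yg <- matrix(0:(N - 1), N, N)
  blob <- exp(-((xg - 40)^2 + (yg - 24)^2) / (2 * 3^2))
  kp <- detect_keypoints(blob)
  expect_gte(nrow(kp), 1)
  d <- sqrt((kp$x - 40)^2 + (kp$y - 24)^2)
  expect_lt(min(d), 2)
  best <- which.min(d)
  # detected scale within one pyramid level (factor 2^(1/3)) of sigma = 3
  expect_lt(abs(log(kp$scale[best] / 3)), log(2^(1 / 3)) + 1e-9)

  # a long straight step edge yields no keypoints
  edge <- matrix(0, 64, 64); edge[, 33:64] <- 1
  expect_equal(nrow(detect_keypoints(edge)), 0)

  expect_error(detect_keypoints(matrix(0, 16, 16)), "32 x 32")
})

test_that("descriptors are deterministic, unit-norm and gain-invariant", {
  set.seed(9)
  img <- tomogate:::cpp_gauss_blur(matrix(runif(64 * 64), 64), 1.2)
  kp <- detect_keypoints(img)
  expect_gt(nrow(kp), 5)
  d1 <- describe_keypoints(img, kp)
  d2 <- describe_keypoints(img, kp)
  expect_identical(d1$descriptors, d2$descriptors)
  expect_equal(sqrt(rowSums(d1$descriptors^2)),
               rep(1, nrow(d1$descriptors)), tolerance = 1e-9)

  # affine intensity gain leaves normalised descriptors unchanged
  d3 <- describe_keypoints(2 * img + 0.5, kp)
  expect_equal(d1$descriptors, d3$descriptors, tolerance = 1e-6)
})

test_that("the full chain is rotation-tolerant on a textured image", {
  set.seed(12)
  img <- tomogate:::cpp_gauss_blur(matrix(runif(64 * 64), 64), 1.2)
  tf <- similarity_transform(1, 30 * pi / 180, c(10, -8))
  img2 <- warp(img, tf, fill = mean(img))
  f1 <- describe_keypoints(img, detect_keypoints(img))
  f2 <- describe_keypoints(img2, detect_keypoints(img2))
  m <- match_nn(f1$descriptors, f2$descriptors)
  expect_gte(nrow(m), 4)
  est <- ransac_similarity(m, as.matrix(f1$keypoints[, c("x", "y")]),
                           as.matrix(f2$keypoints[, c("x", "y")]),
                           seed = 4)
  expect_lt(abs(est$transform$theta - 30 * pi / 180), 3 * pi / 180)
  expect_lt(abs(est$transform$s - 1), 0.05)
})

test_that("match_nn equals a brute-force oracle and handles degeneracies", {
  set.seed(21)
  d1 <- matrix(rnorm(20 * 16), 20); d1 <- d1 / sqrt(rowSums(d1^2))
  d2 <- matrix(rnorm(30 * 16), 30); d2 <- d2 / sqrt(rowSums(d2^2))
  m <- match_nn(d1, d2, ratio_threshold = 0.8)
  expect_equal(nrow(m), oracle_match_count(d1, d2, 0.8))

  # self-match: every keypoint matches its own copy at distance 0
  m_self <- match_nn(d1, d1, ratio_threshold = 0.8)
  expect_equal(m_self$i, m_self$j)
  expect_lt(max(m_self$dist), 1e-6)
  expect_equal(nrow(m_self), nrow(d1))

  # single candidate: absolute-distance fallback
  m1 <- match_nn(d1[1, , drop = FALSE], d1[1, , drop = FALSE])
  expect_equal(nrow(m1), 1)
  far <- matrix(10, 1, 16)
  expect_equal(nrow(match_nn(far, d1[1, , drop = FALSE])), 0)
  expect_equal(nrow(match_nn(matrix(0, 0, 16), d2)), 0)
})

test_that("ransac_similarity recovers planted transforms", {
  set.seed(5)
  tf <- similarity_transform(2, 30 * pi / 180, c(5, -3))

  # identity correspondences
  p <- matrix(runif(60, 0, 50), 30, 2)
  est0 <- ransac_similarity(NULL, p, p, seed = 2)
  expect_equal(est0$transform$s, 1, tolerance = 1e-9)
  expect_equal(est0$transform$theta, 0, tolerance = 1e-9)
  expect_equal(est0$transform$t, c(0, 0), tolerance = 1e-9)

  # 50 exact correspondences
  p1 <- matrix(runif(100, 0, 60), 50, 2)
  est <- ransac_similarity(NULL, p1, transform_points(tf, p1), seed = 3)
  expect_equal(est$transform$s, 2, tolerance = 1e-6)
  expect_equal(est$transform$theta, 30 * pi / 180, tolerance = 1e-6)
  expect_equal(est$transform$t, c(5, -3), tolerance = 1e-6)

  # 30% gross outliers: parameters recovered, outliers excluded
  n <- 60
  p1 <- matrix(runif(2 * n, 0, 60), n, 2)
  p2 <- transform_points(tf, p1)
  out_idx <- sample(n, round(0.3 * n))
  p2[out_idx, ] <- matrix(runif(2 * length(out_idx), 0, 120),
                          length(out_idx), 2)
  est <- ransac_similarity(NULL, p1, p2, seed = 7)
  expect_lt(abs(est$transform$s - 2), 0.01)
  expect_lt(abs(est$transform$theta - 30 * pi / 180), 0.2 * pi / 180)
  expect_lt(max(abs(est$transform$t - c(5, -3))), 0.5)
  expect_false(any(est$inliers[out_idx]))

  # reproducibility under a fixed seed
  estb <- ransac_similarity(NULL, p1, p2, seed = 7)
  expect_identical(est$transform$H, estb$transform$H)

  expect_error(ransac_similarity(NULL, p1[1, , drop = FALSE],
                                 p2[1, , drop = FALSE]), "at least 2")
  # pure noise: consensus stays below the floor
  set.seed(8)
  expect_error(ransac_similarity(NULL, matrix(runif(40, 0, 60), 20),
                                 matrix(runif(40, 0, 60), 20),
                                 inlier_px = 0.05, seed = 9),
               "alignment failure")
})

test_that("align_sequence recovers planted per-frame jitter", {
  acq <- small_acquisition(n_angles = 2, edge_enhance = TRUE)
  base <- acq$stacks[[1]][, , 3]

  # identical frames: all cumulative transforms are the identity
  al_id <- align_sequence(list(base, base, base), seed = 2)
  for (tfm in al_id$transforms) {
    expect_equal(tfm$s, 1, tolerance = 1e-3)
    expect_lt(max(abs(tfm$t)), 0.2)
  }

  # jittered copies of one frame: cumulative transforms match the planted
  # ground truth within half a pixel
  set.seed(31)
  jit <- lapply(1:8, function(a) if (a == 1) similarity_transform() else
    similarity_transform(1 + runif(1, -0.02, 0.02),
                         runif(1, -2, 2) * pi / 180, runif(2, -3, 3)))
  frames <- lapply(jit, function(J) warp(base, J, fill = 1))
  al <- align_sequence(frames, seed = 3)
  expect_length(al$failed_pairs, 0)
  for (a in 2:8) {
    gt <- invert_transform(jit[[a]])
    expect_lt(max(abs(al$transforms[[a]]$t - gt$t)), 0.5)
    expect_lt(abs(al$transforms[[a]]$theta - gt$theta), 0.5 * pi / 180)
    expect_lt(abs(al$transforms[[a]]$s - gt$s), 0.01)
  }
})

test_that("a failed link falls back to identity and is reported", {
  acq <- small_acquisition(n_angles = 2, edge_enhance = TRUE)
  base <- acq$stacks[[1]][, , 3]
  flat <- matrix(1, 64, 64)           # no keypoints on frame 3
  frames <- list(base, base, flat, base, base)
  ws <- testthat::capture_warnings(al <- align_sequence(frames, seed = 2))
  expect_true(any(grepl("identity link", ws)))
  expect_true(3 %in% al$failed_pairs)
  expect_equal(al$transforms[[3]]$H, al$transforms[[2]]$H)
})
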