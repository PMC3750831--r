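# Breathing-phantom acquisition simulator.

test_that("geometry invariants are enforced and defaults match the set-up", {
  g <- acquisition_geometry()
  expect_equal(g$R1, 34)
  expect_equal(g$R2, 1.2)
  expect_equal(g$pixel_pitch, 13e-6)
  expect_equal(g$n_angles, 180L)
  expect_equal(g$frames_per_angle, 20L)
  # 25 keV is about 0.5 Angstrom
  expect_equal(g$wavelength, 4.95937e-11, tolerance = 1e-5)
  expect_equal(effective_distance(g), 34 * 1.2 / 35.2)

  expect_error(acquisition_geometry(R1 = -1), "R1")
  expect_error(acquisition_geometry(pixel_pitch = 0), "pixel_pitch")
  expect_error(acquisition_geometry(n_angles = 400, angle_step = 1),
               "half rotation")
})

test_that("the full acquisition has the stated sampling structure", {
  geom <- acquisition_geometry(n_angles = 6, angle_step = 3,
                               frames_per_angle = 20)
  acq <- make_breathing_phantom(N = 32, geometry = geom, period = 10,
                                amplitude = 0.04, jitter = FALSE,
                                edge_enhance = FALSE, seed = 1)
  expect_length(acq$stacks, 6)
  expect_equal(dim(acq$stacks[[1]]), c(32, 32, 20))
  # 180 angles x 20 frames would give 3600 frames in the full set-up
  g180 <- acquisition_geometry()
  expect_equal(g180$n_angles * g180$frames_per_angle, 3600L)

  expect_error(make_breathing_phantom(N = 8), "N must")
  expect_error(make_breathing_phantom(N = 32, period = 1), "period")
})

test_that("amplitude zero freezes the phantom; same seed is bit-identical", {
  geom <- acquisition_geometry(n_angles = 3, angle_step = 3,
                               frames_per_angle = 6)
  acq <- make_breathing_phantom(N = 32, geometry = geom, period = 3,
                                amplitude = 0, jitter = FALSE, seed = 4)
  for (f in 2:6)
    expect_identical(acq$stacks[[2]][, , f], acq$stacks[[2]][, , 1])

  acq2 <- make_breathing_phantom(N = 32, geometry = geom, period = 3,
                                 amplitude = 0, jitter = FALSE, seed = 4)
  expect_identical(acq$stacks, acq2$stacks)

  # with noise, the same seed still reproduces exactly
  a3 <- make_breathing_phantom(N = 32, geometry = geom, period = 3,
                               amplitude = 0.03, noise_photons = 500,
                               seed = 9)
  a4 <- make_breathing_phantom(N = 32, geometry = geom, period = 3,
                               amplitude = 0.03, noise_photons = 500,
                               seed = 9)
  expect_identical(a3$stacks, a4$stacks)
})

test_that("ground-truth labels mark the sampled sine extremes", {
  # period 10 over 20 frames: two cycles, extremes tied to the earlier frame
  labels <- tomogate:::breathing_labels(20, 10, 0.04)
  expect_equal(which(labels == "max_expansion"), c(3, 13))
  expect_equal(which(labels == "min_contraction"), c(8, 18))
  expect_equal(sum(labels == "max_expansion"), 2)

  # exactly one max and one min per complete cycle, any period
  for (per in c(5, 7, 9)) {
    lab <- tomogate:::breathing_labels(20, per, 0.1)
    n_cyc <- 20 %/% per
    expect_equal(sum(lab == "max_expansion"), n_cyc)
    expect_equal(sum(lab == "min_contraction"), n_cyc)
  }
})

test_that("projection of a centred disk matches the analytic chord length", {
  N <- 64; r <- 20
  cc <- (N - 1) / 2
  disk <- outer(0:(N - 1), 0:(N - 1),
                function(i, j) (i - cc)^2 + (j - cc)^2 <= r^2) * 1
  geom <- acquisition_geometry(n_angles = 3, angle_step = 45)
  fr <- simulate_projection(disk, 30, geom)
  prof <- fr[33, ]                    # any row: flat envelope by default
  s <- (0:(N - 1)) - cc
  chord <- ifelse(abs(s) < r, 2 * sqrt(pmax(r^2 - s^2, 0)), 0)
  # discretisation error concentrates at the rim; compare away from it
  inner <- abs(s) < r - 2
  expect_lt(max(abs(prof[inner] - chord[inner])), 0.05 * max(chord))
  expect_lt(mean(abs(prof - chord)), 0.01 * max(chord))

  expect_equal(simulate_projection(matrix(0, N, N), 10, geom),
               matrix(0, N, N))
  expect_error(simulate_projection(disk, 200, geom), "angle")
  expect_error(simulate_projection(-disk - 1, 10, geom), "non-negative")
  expect_error(simulate_projection(disk, 10, geom, noise_photons = -5),
               "noise_photons")
})

test_that("edge enhancement creates an overshoot/undershoot fringe pair", {
  N <- 64
  slice <- matrix(0, N, N); slice[, 1:32] <- 0.5   # half-plane object
  geom <- acquisition_geometry()
  plain <- simulate_projection(slice, 0, geom)[33, ]
  enh <- simulate_projection(slice, 0, geom, edge_enhance = TRUE,
                             phase_scale = 0.005)[33, ]
  # the plain projection is a monotone-edged profile; the edge-enhanced
  # intensity swings above and below its background near the step
  edge <- which.max(abs(diff(plain)))
  win <- max(1, edge - 5):min(N, edge + 5)
  expect_gt(max(enh[win]), 1.02)
  expect_lt(min(enh[win]), 0.98)
  # far from the step the intensity stays near the unit background
  # (slowly decaying Fresnel ripple of a few percent remains)
  expect_lt(abs(enh[N - 2] - 1), 0.05)
  # without enhancement the step profile never over- or undershoots its
  # two plateau levels
  expect_lte(max(plain), max(plain[c(5, 60)]) + 1e-9)
  expect_gte(min(plain), min(plain[c(5, 60)]) - 1e-9)
})

test_that("Poisson noise has the stated flux and only adds noise", {
  geom <- acquisition_geometry()
  flux <- 1000
  flat <- simulate_projection(matrix(0, 64, 64), 0, geom,
                              edge_enhance = TRUE, noise_photons = flux,
                              seed = 3)
  # counts are flux * frame; the flat field has unit intensity
  se <- sqrt(1 / (flux * length(flat)))
  expect_lt(abs(mean(flat) - 1), 3 * se)
  expect_gt(sd(flat), 0)
})

test_that("per-angle jitter is recorded and angle 1 is the reference", {
  acq <- small_acquisition(n_angles = 4, jitter = TRUE)
  expect_equal(acq$truth$jitter[[1]]$s, 1)
  expect_equal(acq$truth$jitter[[1]]$t, c(0, 0))
  for (a in 2:4) {
    j <- acq$truth$jitter[[a]]
    expect_lte(abs(j$theta), 2 * pi / 180 + 1e-12)
    expect_lte(max(abs(j$t)), 3)
    expect_lte(abs(j$s - 1), 0.02)
  }
})

test_that("phantoms are non-negative with area-weighted edges", {
  P <- shepp_logan(64)
  expect_true(all(P >= 0))
  expect_equal(dim(P), c(64, 64))
  # anti-aliasing: boundary pixels take intermediate values
  expect_gt(sum(P > 0.02 & P < 0.9), 50)
  C <- chest_phantom(64)
  expect_true(all(C >= 0))
  expect_equal(max(C), 1)
})
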