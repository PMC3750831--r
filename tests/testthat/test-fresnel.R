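# Wavefield propagation, the weak-phase forward model and phase retrieval.

pitch <- 13e-6
lam <- kev_to_wavelength(25)

test_that("propagation is unitary, invertible and the identity at z = 0", {
  set.seed(1)
  N <- 64
  U <- matrix(complex(real = rnorm(N * N), imaginary = rnorm(N * N)), N)
  wf <- wavefield(U, pitch, lam)

  w0 <- propagate(wf, 0)
  expect_lt(max(Mod(w0$U - U)), 1e-12 * max(Mod(U)))

  for (z in c(0.3, 5, -2)) {
    wz <- propagate(wf, z)
    expect_lt(abs(sum(Mod(wz$U)^2) - sum(Mod(U)^2)) / sum(Mod(U)^2), 1e-10)
    back <- propagate(wz, z, "backward")
    expect_lt(max(Mod(back$U - U)) / max(Mod(U)), 1e-10)
  }

  expect_error(wavefield(U, 0, lam), "pixel_pitch")
  expect_error(wavefield(U, pitch, -1), "wavelength")
  expect_warning(propagate(wf, 1e5), "sampling limit")
})

test_that("a Gaussian beam spreads by the closed-form width", {
  N <- 128
  w0 <- 8 * pitch
  cc <- (N - 1) / 2
  r2 <- outer(((0:(N - 1)) - cc)^2, ((0:(N - 1)) - cc)^2, `+`) * pitch^2
  G <- exp(-r2 / w0^2)
  zR <- pi * w0^2 / lam
  z <- 0.4 * zR                       # within the grid sampling limit
  Iz <- intensity(propagate(wavefield(G, pitch, lam), z))
  w_emp <- sqrt(2 * sum(Iz * r2) / sum(Iz))
  w_th <- w0 * sqrt(1 + (z / zR)^2)
  expect_lt(abs(w_emp - w_th) / w_th, 0.01)
})

test_that("tie_intensity matches hand-computable Laplacians", {
  # constant phase: I identically 1
  expect_equal(tie_intensity(matrix(2, 16, 16), 1, lam, 1),
               matrix(1, 16, 16))

  # paraboloid: interior Laplacian is exactly 2a
  N <- 32; a <- 1e-4
  xi <- matrix(0:(N - 1), N, N, byrow = TRUE)
  yi <- matrix(0:(N - 1), N, N)
  I <- tie_intensity(a * (xi^2 + yi^2) / 2, z = 1, lam, 1)
  expect_equal(I[3:(N - 2), 3:(N - 2)],
               matrix(1 + lam / (2 * pi) * 2 * a, N - 4, N - 4),
               tolerance = 1e-12)

  # sinusoid: response proportional to minus the sinusoid, with the
  # discrete spectral gain 2 - 2 cos(2 pi f) (unit z and wavelength keep
  # the comparison at O(1))
  f <- 4 / N
  Phi <- 1e-3 * sin(2 * pi * f * xi)
  I <- tie_intensity(Phi, z = 2 * pi, wavelength = 1, pixel_pitch = 1)
  interior <- I[, 5:(N - 4)] - 1
  pred <- -1e-3 * (2 - 2 * cos(2 * pi * f)) * sin(2 * pi * f * xi[, 5:(N - 4)])
  expect_lt(max(abs(interior - pred)), 1e-6 * max(abs(pred)))

  # linear in the phase (unit-scale z and wavelength so the perturbation
  # is O(1) and the comparison is not dominated by cancellation)
  set.seed(2)
  A <- matrix(rnorm(64), 8); B <- matrix(rnorm(64), 8)
  expect_equal(tie_intensity(A + 2 * B, 2 * pi, 1) - 1,
               (tie_intensity(A, 2 * pi, 1) - 1) +
                 2 * (tie_intensity(B, 2 * pi, 1) - 1),
               tolerance = 1e-12)
})

test_that("weak-phase Fourier retrieval inverts the forward propagation", {
  N <- 64
  z <- (2.5 * pitch)^2 / lam
  phi <- matrix(0, N, N)
  phi[20:45, 25:40] <- 0.05           # sharp box phase
  I <- intensity(propagate(wavefield(exp(1i * phi), pitch, lam), z))
  got <- ctf_retrieve(I, z, lam, pitch, reg = 1e-3)
  want <- phi - mean(phi)
  expect_lt(sqrt(mean((got - want)^2)) / sd(phi), 0.05)
})

test_that("error reduction: degenerate inputs and fixed-point behaviour", {
  N <- 32
  supp <- matrix(FALSE, N, N); supp[10:22, 10:22] <- TRUE

  # zero intensity: amplitude is zero after one iteration
  out <- error_reduction_retrieve(matrix(0, N, N), supp, 1, lam, pitch,
                                  max_iters = 1)
  expect_equal(max(Mod(out$field$U)), 0)
  expect_error(error_reduction_retrieve(matrix(0, N, N),
                                        matrix(FALSE, N, N), 1, lam, pitch),
               "degenerate")

  # initialising with the true field is a fixed point
  phi <- matrix(0, N, N); phi[12:20, 12:20] <- 0.1
  U0 <- wavefield(supp * exp(1i * phi), pitch, lam)
  z <- (2 * pitch)^2 / lam
  I <- intensity(propagate(U0, z))
  out <- error_reduction_retrieve(I, supp, z, lam, pitch, max_iters = 1,
                                  init = U0)
  expect_lt(out$residuals[1], 1e-10)
})

test_that("error reduction converges on a weak-phase phantom, monotonically", {
  N <- 64
  cc <- (N - 1) / 2
  supp <- outer(((0:(N - 1)) - cc)^2, ((0:(N - 1)) - cc)^2, `+`) < 24^2
  phi <- matrix(0, N, N)
  phi[25:40, 20:45] <- 0.1            # max 0.1 rad
  phi <- phi * supp
  z <- (2.5 * pitch)^2 / lam
  I <- intensity(propagate(wavefield(supp * exp(1i * phi), pitch, lam), z))

  out <- error_reduction_retrieve(I, supp, z, lam, pitch, max_iters = 100)
  expect_lt(utils::tail(out$residuals, 1), 1e-2)
  expect_true(all(diff(out$residuals) <= 1e-10))

  # the combined interface returns a phase map
  ph <- retrieve_phase(I, z, lam, pitch, method = "error_reduction",
                       support = supp, max_iters = 30)
  expect_equal(dim(ph), c(N, N))
})
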