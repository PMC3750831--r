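# Complex wavefield propagation (angular spectrum, Fresnel approximation),
# the weak-phase transport-of-intensity forward model, and error-reduction
# phase retrieval.

#' Construct a complex wavefield on a pixel grid
#'
#' A paraxial optical field \eqn{U(x,y) = \rho \exp(i\delta)} sampled on an
#' N x N grid with a physical pixel pitch, at wavelength `wavelength` and
#' axial plane `z`. The measurable intensity is \eqn{I = |U|^2}.
#'
#' @param U Complex (or real) matrix of field values.
#' @param pixel_pitch Grid spacing in metres.
#' @param wavelength Wavelength in metres.
#' @param z Axial coordinate of the plane in metres (bookkeeping only).
#' @return An object of class `wavefield`.
#' @export
wavefield <- function(U, pixel_pitch, wavelength, z = 0) {
  if (pixel_pitch <= 0) stop("pixel_pitch must be positive")
  if (wavelength <= 0) stop("wavelength must be positive")
  U <- as.matrix(U)
  storage.mode(U) <- "complex"
  structure(list(U = U, pixel_pitch = pixel_pitch,
                 wavelength = wavelength, z = z),
            class = "wavefield")
}

#' Intensity of a wavefield
#' @param field A [wavefield()].
#' @return Real matrix `|U|^2`.
#' @export
intensity <- function(field) Mod(field$U)^2

#' @export
print.wavefield <- function(x, ...) {
  cat(sprintf("wavefield %d x %d, pitch %.3g m, lambda %.3g m, z = %.3g m\n",
              nrow(x$U), ncol(x$U), x$pixel_pitch, x$wavelength, x$z))
  invisible(x)
}

# centred FFT frequencies in cycles per metre
fft_freqs <- function(n, pitch) {
  (((seq_len(n) - 1) + n %/% 2) %% n - n %/% 2) / (n * pitch)
}

#' Fresnel propagation of a wavefield
#'
#' Propagates the field by `distance` using the angular-spectrum transfer
#' function in the Fresnel (paraxial) approximation,
#' \eqn{H(f_x,f_y) = \exp[+i\pi\lambda z (f_x^2+f_y^2)]} (the time
#' convention under which a weak phase object \eqn{\exp(i\Phi)} produces
#' \eqn{I \approx 1 + (\lambda z/2\pi)\nabla^2\Phi}). The transfer
#' function has unit modulus, so propagation is unitary on the grid and
#' `propagate(propagate(U, z), -z)` recovers the input to round-off.
#'
#' @param field A [wavefield()].
#' @param distance Propagation distance in metres (signed).
#' @param direction `"forward"` or `"backward"`; backward propagation over
#'   `z` equals forward propagation over `-z`.
#' @return The propagated [wavefield()].
#' @details The quadratic chirp is adequately sampled only when
#'   `|z| <= N * pitch^2 / lambda`; a warning is issued beyond that.
#' @export
propagate <- function(field, distance, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  z <- if (direction == "backward") -distance else distance
  N <- nrow(field$U); M <- ncol(field$U)
  zmax <- min(N, M) * field$pixel_pitch^2 / field$wavelength
  if (abs(z) > zmax)
    warning(sprintf(
      "propagation distance %.3g m exceeds the grid sampling limit %.3g m",
      abs(z), zmax))
  fx <- fft_freqs(M, field$pixel_pitch)
  fy <- fft_freqs(N, field$pixel_pitch)
  f2 <- outer(fy^2, fx^2, `+`)
  H <- exp(1i * pi * field$wavelength * z * f2)
  Uz <- stats::fft(stats::fft(field$U) * H, inverse = TRUE) / (N * M)
  wavefield(Uz, field$pixel_pitch, field$wavelength, field$z + z)
}

#' Weak-phase intensity after propagation (transport-of-intensity model)
#'
#' For a weakly absorbing object under unit-amplitude plane-wave
#' illumination, the intensity a distance `z` downstream is, to first order,
#' \deqn{I(x,y,z) \approx 1 + \frac{\lambda z}{2\pi}\nabla_\perp^2 \Phi(x,y,0),}
#' which is the linearised transport-of-intensity relation. The transverse
#' Laplacian is discretised with the 5-point stencil (replicated edges).
#'
#' @param phase Real matrix, object-plane phase \eqn{\Phi(x,y,0)} in radians.
#' @param z Propagation distance in metres.
#' @param wavelength Wavelength in metres.
#' @param pixel_pitch Grid spacing in metres (default 1: phase already on a
#'   unit grid).
#' @return Intensity image (background 1).
#' @export
tie_intensity <- function(phase, z, wavelength, pixel_pitch = 1) {
  phase <- as.matrix(phase)
  if (!all(is.finite(phase))) stop("phase must be finite everywhere")
  1 + (wavelength * z / (2 * pi)) * laplacian5(phase) / pixel_pitch^2
}

# 5-point Laplacian with replicated (Neumann) edges
laplacian5 <- function(m) {
  up <- rbind(m[1, , drop = FALSE], m[-nrow(m), , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], m[nrow(m), , drop = FALSE])
  lf <- cbind(m[, 1, drop = FALSE], m[, -ncol(m), drop = FALSE])
  rt <- cbind(m[, -1, drop = FALSE], m[, ncol(m), drop = FALSE])
  up + dn + lf + rt - 4 * m
}

#' Direct (Fourier) inversion of the weak-phase intensity model
#'
#' Convenience inverse of [tie_intensity()]: recovers the object-plane phase
#' from one near-field intensity by Fourier division of the Laplacian
#' symbol, with Tikhonov regularisation at low frequencies. The iterative
#' alternative is [error_reduction_retrieve()].
#'
#' @param intensity_img Measured intensity (background approximately 1).
#' @param z,wavelength,pixel_pitch As in [tie_intensity()].
#' @param reg Absolute Tikhonov regularisation added to the squared symbol
#'   (default `1e-3`; raise it for noisy data).
#' @return Phase map in radians, zero-mean.
#' @export
tie_retrieve <- function(intensity_img, z, wavelength, pixel_pitch = 1,
                         reg = 1e-3) {
  weak_phase_inverse(intensity_img, z, wavelength, pixel_pitch, reg,
                     model = "tie")
}

#' Contrast-transfer-function (CTF) phase retrieval
#'
#' Exact linear inversion for a weak pure-phase object at any Fresnel
#' number: in Fourier space the near-field intensity obeys
#' \eqn{\widehat{I-1}(f) = -2\sin(\pi\lambda z |f|^2)\,\hat\Phi(f)}, whose
#' small-argument limit is the transport-of-intensity model of
#' [tie_retrieve()]. Preferred when the first Fresnel fringe is comparable
#' to the feature size (the edge-enhancement regime).
#'
#' @inheritParams tie_retrieve
#' @return Phase map in radians, zero-mean.
#' @export
ctf_retrieve <- function(intensity_img, z, wavelength, pixel_pitch = 1,
                         reg = 1e-3) {
  weak_phase_inverse(intensity_img, z, wavelength, pixel_pitch, reg,
                     model = "ctf")
}

# shared Fourier-division inverse of the two linear weak-phase models
weak_phase_inverse <- function(intensity_img, z, wavelength, pixel_pitch,
                               reg, model) {
  m <- as.matrix(intensity_img) - 1
  N <- nrow(m); M <- ncol(m)
  fx <- fft_freqs(M, pixel_pitch)
  fy <- fft_freqs(N, pixel_pitch)
  f2 <- outer(fy^2, fx^2, `+`)
  sym <- if (model == "tie") {
    (wavelength * z / (2 * pi)) * (-4 * pi^2 * f2)
  } else {
    -2 * sin(pi * wavelength * z * f2)
  }
  den <- sym^2 + reg^2
  Fphi <- stats::fft(m) * sym / den
  phi <- Re(stats::fft(Fphi, inverse = TRUE)) / (N * M)
  phi - mean(phi)
}

#' Error-reduction phase retrieval
#'
#' Alternating-projection retrieval of the object-plane complex amplitude
#' from one detector-plane intensity. Each iteration performs the four
#' classic steps: (1) forward Fresnel transform the current object-plane
#' estimate; (2) replace the modulus of the result with the measured
#' modulus \eqn{\sqrt{I}} (phase kept); (3) backward Fresnel transform;
#' (4) set the amplitude to zero outside the object support. The
#' detector-plane modulus mismatch is non-increasing across iterations and
#' is reported in the diagnostics.
#'
#' @param measured_intensity Non-negative intensity image (detector plane).
#' @param support Logical/0-1 matrix marking the object zone; must contain
#'   at least one pixel.
#' @param z Object-to-detector propagation distance in metres.
#' @param wavelength Wavelength in metres.
#' @param pixel_pitch Grid spacing in metres.
#' @param max_iters Iteration count (default 100).
#' @param init Optional initial [wavefield()] (object plane); default is
#'   unit amplitude, zero phase inside the support.
#' @param tol Early stop when the relative residual change falls below
#'   `tol` (default 0: run all iterations).
#' @return A list: `field` (object-plane [wavefield()]), `residuals`
#'   (relative detector-plane modulus error per iteration), `iterations`.
#' @export
error_reduction_retrieve <- function(measured_intensity, support, z,
                                     wavelength, pixel_pitch = 1,
                                     max_iters = 100, init = NULL, tol = 0) {
  I <- as.matrix(measured_intensity)
  if (any(I < 0)) I[I < 0] <- 0   # noisy preprocessing can dip negative
  S <- as.matrix(support) != 0
  if (!any(S)) {
    if (all(I == 0)) stop("degenerate input: zero intensity and empty support")
    stop("support must contain at least one pixel")
  }
  if (!all(dim(I) == dim(S))) stop("support and intensity shapes differ")
  meas_mod <- sqrt(I)
  mnorm <- sqrt(sum(meas_mod^2))
  U <- if (is.null(init)) {
    wavefield(matrix(as.numeric(S), nrow(S), ncol(S)), pixel_pitch,
              wavelength)
  } else init

  residuals <- numeric(0)
  for (k in seq_len(max_iters)) {
    D <- propagate(U, z, "forward")
    modD <- Mod(D$U)
    res <- sqrt(sum((modD - meas_mod)^2)) / max(mnorm, .Machine$double.eps)
    residuals <- c(residuals, res)
    phase_fac <- ifelse(modD > 0, D$U / modD, 1 + 0i)
    D$U <- meas_mod * phase_fac
    U <- propagate(D, z, "backward")
    U$U[!S] <- 0 + 0i
    U$z <- 0
    if (k > 1 && tol > 0 &&
        abs(residuals[k - 1] - res) < tol * max(res, .Machine$double.eps))
      break
  }
  list(field = U, residuals = residuals, iterations = length(residuals))
}

#' Retrieve a phase map from a near-field intensity
#'
#' Single entry point over the two retrieval routes: the iterative
#' error-reduction algorithm (default) or the direct weak-phase Fourier
#' inversion.
#'
#' @param intensity_img Measured intensity image.
#' @param z,wavelength,pixel_pitch Propagation parameters.
#' @param method `"error_reduction"`, `"ctf"` or `"tie"`.
#' @param support Object support for error reduction; default: all pixels.
#' @param ... Passed to the underlying method.
#' @return Phase map in radians.
#' @export
retrieve_phase <- function(intensity_img, z, wavelength, pixel_pitch = 1,
                           method = c("error_reduction", "ctf", "tie"),
                           support = NULL, ...) {
  method <- match.arg(method)
  if (method == "tie")
    return(tie_retrieve(intensity_img, z, wavelength, pixel_pitch, ...))
  if (method == "ctf")
    return(ctf_retrieve(intensity_img, z, wavelength, pixel_pitch, ...))
  if (is.null(support))
    support <- matrix(TRUE, nrow(intensity_img), ncol(intensity_img))
  out <- error_reduction_retrieve(intensity_img, support, z, wavelength,
                                  pixel_pitch, ...)
  Arg(out$field$U)
}
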