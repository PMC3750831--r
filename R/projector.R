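# Parallel-beam CT forward model: ray-driven (Siddon) line integrals, the
# exact adjoint, and the filtered-back-projection baseline.
#
# Coordinate convention, used everywhere: the image is an N x N matrix
# indexed (row t1, col t2), 0-based in the geometry; rotation is about the
# grid centre (N-1)/2; angles are measured in degrees counterclockwise from
# the +x (column) axis; detector bin pitch equals the pixel pitch.

#' Sensing model (projection geometry)
#'
#' Describes the measurement matrix implicitly: `N x N` image grid,
#' projection angles, and `n_bins` detector bins per angle. Rows of the
#' matrix (one per ray) are realised on the fly by Siddon ray tracing with
#' exact intersection-length weights.
#'
#' @param N Image grid size.
#' @param angles Projection angles in degrees, in `[0, 180)`.
#' @param n_bins Detector bins per angle (default `N`).
#' @return Object of class `sensing_model`.
#' @export
sensing_model <- function(N, angles, n_bins = N) {
  if (length(angles) < 1) stop("at least one angle is required")
  if (any(angles < 0 | angles >= 180)) stop("angles must be in [0, 180)")
  structure(list(type = "radon", N = as.integer(N),
                 angles = as.numeric(angles),
                 n_bins = as.integer(n_bins),
                 M = length(angles) * as.integer(n_bins)),
            class = "sensing_model")
}

#' Dense sensing model
#'
#' A sensing model whose measurement matrix is given explicitly: row `r`
#' holds the coefficients `phi_{r,i}` over the `N^2` pixels (column-major).
#' Useful for small systems and for testing the row-action solver outside
#' the CT geometry.
#'
#' @param Phi `M x N^2` matrix.
#' @param N Image grid size; defaults to `sqrt(ncol(Phi))`.
#' @return Object of class `sensing_model` with `type = "dense"`.
#' @export
dense_sensing_model <- function(Phi, N = NULL) {
  Phi <- as.matrix(Phi)
  if (is.null(N)) N <- as.integer(round(sqrt(ncol(Phi))))
  if (N * N != ncol(Phi)) stop("Phi must have N^2 columns")
  structure(list(type = "dense", N = as.integer(N), Phi = Phi,
                 M = nrow(Phi)), class = "sensing_model")
}

# forward projection through either sensing-model backend
model_forward <- function(model, x) {
  if (model$type == "dense") as.vector(model$Phi %*% as.vector(x))
  else as.vector(t(cpp_radon(x, model$angles * pi / 180, model$n_bins)))
}

#' Sinogram container
#'
#' @param data `n_angles x n_bins` matrix of ray sums.
#' @param angles Angles in degrees.
#' @return Object of class `sinogram`.
#' @export
sinogram <- function(data, angles) {
  data <- as.matrix(data)
  if (nrow(data) != length(angles))
    stop("sinogram rows must match the angle list")
  if (!all(is.finite(data))) stop("sinogram values must be finite")
  structure(list(data = data, angles = as.numeric(angles),
                 n_bins = ncol(data)), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("sinogram: %d angles x %d bins\n", nrow(x$data), x$n_bins))
  invisible(x)
}

#' Forward projection (parallel-beam Radon transform)
#'
#' Computes the ray sums `y_r = sum_i phi_{r,i} x_i` where `phi_{r,i}` is
#' the exact intersection length of ray `r` with pixel `i` (Siddon
#' traversal). Linear in the image.
#'
#' @param image Square matrix.
#' @param angles Projection angles in degrees, in `[0, 180)`.
#' @param n_bins Detector bins (default `nrow(image)`).
#' @return A [sinogram()].
#' @export
radon_forward <- function(image, angles, n_bins = nrow(image)) {
  image <- as.matrix(image)
  if (nrow(image) != ncol(image)) stop("image must be square")
  if (length(angles) < 1) stop("at least one angle is required")
  if (any(angles < 0 | angles >= 180)) stop("angles must be in [0, 180)")
  sinogram(cpp_radon(image, angles * pi / 180, as.integer(n_bins)), angles)
}

#' Backprojection (exact adjoint of the forward projector)
#'
#' Applies the transpose of the sensing matrix: each ray value is smeared
#' back over the pixels it crosses, weighted by the same intersection
#' lengths as [radon_forward()], so `<Ax, y> = <x, A'y>` holds to round-off.
#'
#' @param sino A [sinogram()].
#' @param model A [sensing_model()] (defines `N`); its angles and bins must
#'   match the sinogram.
#' @return `N x N` matrix.
#' @export
back_project <- function(sino, model) {
  if (!identical(length(sino$angles), length(model$angles)) ||
      any(sino$angles != model$angles) || sino$n_bins != model$n_bins)
    stop("sinogram geometry does not match the sensing model")
  cpp_backproject(sino$data, sino$angles * pi / 180, model$N)
}

# frequency response of the discrete ramp filter (Ram-Lak), from its exact
# spatial-domain samples; optional smoothing windows
ramp_response <- function(n, filter) {
  h <- numeric(n)
  k <- c(0:(n / 2), -(n / 2 - 1):-1)
  h[k == 0] <- 0.25
  odd <- k %% 2 != 0
  h[odd] <- -1 / (pi * k[odd])^2
  H <- Re(stats::fft(h))
  f <- abs(k) / (n / 2)            # normalised frequency, 1 at Nyquist
  w <- switch(filter,
              ramp = rep(1, n),
              "shepp-logan" = ifelse(f == 0, 1, sin(pi * f / 2) / (pi * f / 2)),
              hann = 0.5 * (1 + cos(pi * f)))
  H * w
}

#' Filtered back projection
#'
#' The analytic baseline reconstruction: each projection is ramp-filtered
#' in the frequency domain (exact discrete Ram-Lak samples, optionally
#' windowed), back-projected with pixel-driven linear interpolation, and
#' scaled by `pi / n_angles`.
#'
#' @param sino A [sinogram()] with at least 2 angles.
#' @param N Output grid size (default `n_bins`).
#' @param filter `"ramp"`, `"shepp-logan"` or `"hann"`.
#' @return `N x N` reconstructed image.
#' @export
fbp <- function(sino, N = sino$n_bins, filter = c("ramp", "shepp-logan",
                                                  "hann")) {
  filter <- match.arg(filter)
  n_ang <- nrow(sino$data)
  if (n_ang < 2) stop("FBP needs at least 2 angles")
  nb <- sino$n_bins
  npad <- 2^ceiling(log2(2 * nb))
  H <- ramp_response(npad, filter)
  filt <- matrix(0, n_ang, nb)
  for (a in seq_len(n_ang)) {
    p <- c(sino$data[a, ], rep(0, npad - nb))
    q <- Re(stats::fft(stats::fft(p) * H, inverse = TRUE)) / npad
    filt[a, ] <- q[seq_len(nb)]
  }
  cpp_backproject_interp(filt, sino$angles * pi / 180, as.integer(N)) *
    (pi / n_ang)
}
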