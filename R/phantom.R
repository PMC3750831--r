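# Synthetic breathing phantom and acquisition simulator. Stands in for the
# (undeposited) live-mouse projections: a 2D "rib cage" slice whose geometry
# scales periodically with a breathing cycle, extruded vertically, projected
# per angle, optionally edge-enhanced by Fresnel propagation, with Poisson
# noise and small per-angle similarity jitter.

#' Piecewise-constant chest-like phantom slice
#'
#' An axial slice used by the breathing simulator: an outer annular "rib
#' cage" ring, two lung fields with bright vessel-like dots, a heart-like
#' ellipse and a spine dot. Piecewise constant, so well suited to
#' total-variation reconstruction tests. Values are refractive phase
#' decrements per unit length (arbitrary units, max 1).
#'
#' @param N Grid size (pixels).
#' @param oversample Sub-pixel rasterisation factor (default 4): the slice
#'   is rendered at `oversample * N` and box-averaged, so ellipse boundaries
#'   carry their exact area weight instead of a binary in/out decision.
#' @return `N x N` non-negative matrix.
#' @export
chest_phantom <- function(N = 64, oversample = 4) {
  if (oversample > 1)
    return(box_downsample(chest_phantom(N * oversample, oversample = 1),
                          oversample))
  cc <- (N - 1) / 2
  u <- ((0:(N - 1)) - cc) / (N / 2)   # columns, in [-1, 1]
  v <- ((0:(N - 1)) - cc) / (N / 2)   # rows
  X <- matrix(u, N, N, byrow = TRUE)
  Y <- matrix(v, N, N)
  r <- sqrt(X^2 + Y^2)
  img <- matrix(0, N, N)
  img[abs(r - 0.72) < 0.07] <- 1.0                       # rib cage ring
  ell <- function(x0, y0, a, b, phi_deg) {
    ph <- phi_deg * pi / 180
    xr <- (X - x0) * cos(ph) + (Y - y0) * sin(ph)
    yr <- -(X - x0) * sin(ph) + (Y - y0) * cos(ph)
    (xr / a)^2 + (yr / b)^2 <= 1
  }
  img[ell(0, 0, 0.60, 0.60, 0)] <- pmax(img[ell(0, 0, 0.60, 0.60, 0)], 0.15)
  img[ell(-0.28, 0.02, 0.22, 0.34, 8)] <- 0.35           # lungs
  img[ell(0.28, 0.02, 0.22, 0.34, -8)] <- 0.35
  img[ell(0.02, 0.28, 0.16, 0.13, 0)] <- 0.55            # heart
  img[ell(0, -0.52, 0.08, 0.08, 0)] <- 0.85              # spine
  vessels <- list(c(-0.30, -0.10), c(-0.22, 0.18), c(0.33, 0.10),
                  c(0.24, -0.18), c(-0.36, 0.05), c(0.18, 0.22),
                  c(-0.15, -0.22), c(0.38, -0.05), c(-0.08, 0.12),
                  c(0.10, -0.30))
  for (k in seq_along(vessels)) {
    d <- vessels[[k]]
    img[ell(d[1], d[2], 0.030 + 0.015 * (k %% 3), 0.030 + 0.012 * (k %% 2),
            20 * k)] <- 0.6 + 0.05 * (k %% 4)            # vessel sections
  }
  img
}

#' Shepp-Logan head phantom (modified contrast)
#'
#' The standard 10-ellipse test phantom with the widely used
#' modified-contrast grey levels (values in `[0, 1]`).
#'
#' @param N Grid size.
#' @param oversample Sub-pixel rasterisation factor (default 4), see
#'   [chest_phantom()].
#' @return `N x N` matrix.
#' @export
shepp_logan <- function(N = 64, oversample = 4) {
  if (oversample > 1)
    return(box_downsample(shepp_logan(N * oversample, oversample = 1),
                          oversample))
  # A, a, b, x0, y0, phi(deg) -- modified (Toft) grey levels
  E <- matrix(c(
     1.00, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.80, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.20, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.20, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.10, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.10, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.10, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.10, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.10, 0.0230, 0.0230,  0.00, -0.6060,   0,
     0.10, 0.0230, 0.0460,  0.06, -0.6050,   0), ncol = 6, byrow = TRUE)
  cc <- (N - 1) / 2
  x <- ((0:(N - 1)) - cc) / (N / 2)
  X <- matrix(x, N, N, byrow = TRUE)
  Y <- matrix(-x, N, N)      # row 1 is the top of the head
  img <- matrix(0, N, N)
  for (k in seq_len(nrow(E))) {
    ph <- E[k, 6] * pi / 180
    xr <- (X - E[k, 4]) * cos(ph) + (Y - E[k, 5]) * sin(ph)
    yr <- -(X - E[k, 4]) * sin(ph) + (Y - E[k, 5]) * cos(ph)
    img <- img + E[k, 1] * ((xr / E[k, 2])^2 + (yr / E[k, 3])^2 <= 1)
  }
  pmax(img, 0)
}

#' Radially scale a slice about its centre
#'
#' Models breathing as isotropic scaling of the slice geometry: the output
#' at radius `r` samples the input at `r / s` (bilinear), so `s > 1` is
#' expansion.
#'
#' @param slice `N x N` matrix.
#' @param s Scale factor (> 0).
#' @return Scaled `N x N` matrix.
#' @export
scale_slice <- function(slice, s) {
  if (s == 1) return(slice)
  N <- nrow(slice); M <- ncol(slice)
  cr <- (N - 1) / 2; ccol <- (M - 1) / 2
  xs <- matrix((0:(M - 1) - ccol) / s + ccol, N, M, byrow = TRUE)
  ys <- matrix((0:(N - 1) - cr) / s + cr, N, M)
  cpp_bilinear_sample(slice, xs, ys)
}

# vertical extrusion profile: smooth window with mild banding so frames have
# 2D structure for keypoint detection; equals 1 at the central row
phantom_envelope <- function(N) {
  y0 <- N %/% 2 + 1
  y <- seq_len(N)
  d <- abs(y - y0) / N
  win <- ifelse(d < 0.28, 1,
                ifelse(d < 0.42, 0.5 * (1 + cos(pi * (d - 0.28) / 0.14)), 0))
  e <- win * (1 + 0.25 * cos(2 * pi * 3 * (y - y0) / N) +
                0.12 * sin(2 * pi * 5 * (y - y0) / N))
  e / e[y0]
}

#' Simulate one projection frame
#'
#' Forms the parallel-beam line-integral projection of a phantom slice at
#' one angle, extrudes it vertically into a 2D frame, and optionally (a)
#' imprints it as the phase of a unit plane wave and propagates the wave
#' over the effective free-space distance so that edge-enhanced intensity
#' contrast appears, and (b) applies Poisson counting noise.
#'
#' @param slice Non-negative `N x N` phantom slice.
#' @param angle Projection angle in degrees, in `[0, 180)`.
#' @param geometry An [acquisition_geometry()].
#' @param envelope Optional length-`N` vertical profile (default all ones).
#' @param edge_enhance If `TRUE`, apply Fresnel propagation over
#'   [effective_distance()] and return the detected intensity (background 1);
#'   otherwise return the raw line integrals.
#' @param noise_photons Mean photon flux per pixel for Poisson noise, or
#'   `NULL` for a noiseless frame. The returned frame stays normalised
#'   (counts divided by the flux).
#' @param phase_scale Radians of phase per unit line integral (default
#'   0.01), controlling how weak the phase object is.
#' @param prop_distance Effective propagation distance (m) for the edge
#'   enhancement. Default `NULL` uses a fringe-resolvable distance,
#'   `(2.5 * pixel_pitch)^2 / wavelength`, so the first Fresnel fringe
#'   spans about 2.5 px on the simulation grid; pass
#'   `effective_distance(geometry)` for the physical distance (whose
#'   fringes are sub-pixel on a coarse desk-scale grid).
#' @param seed Optional RNG seed for the noise.
#' @return `N x N` intensity frame.
#' @export
simulate_projection <- function(slice, angle, geometry,
                                envelope = NULL, edge_enhance = FALSE,
                                noise_photons = NULL, phase_scale = 0.01,
                                prop_distance = NULL, seed = NULL) {
  slice <- as.matrix(slice)
  if (any(slice < 0)) stop("slice must be non-negative")
  if (angle < 0 || angle >= 180) stop("angle must be in [0, 180)")
  if (!is.null(noise_photons) && noise_photons <= 0)
    stop("noise_photons must be positive")
  N <- nrow(slice)
  p <- as.vector(cpp_radon(slice, angle * pi / 180, N))
  if (is.null(envelope)) envelope <- rep(1, N)
  frame <- outer(envelope, p)
  if (edge_enhance) {
    if (is.null(prop_distance))
      prop_distance <- (2.5 * geometry$pixel_pitch)^2 / geometry$wavelength
    wf <- wavefield(exp(1i * phase_scale * frame),
                    pixel_pitch = geometry$pixel_pitch,
                    wavelength = geometry$wavelength)
    frame <- intensity(propagate(wf, prop_distance))
  }
  if (!is.null(noise_photons)) {
    add_noise <- function() {
      cnt <- stats::rpois(length(frame), noise_photons * pmax(frame, 0))
      matrix(cnt / noise_photons, nrow(frame), ncol(frame))
    }
    frame <- if (is.null(seed)) add_noise() else with_seed(seed, add_noise())
  }
  frame
}

# per-frame breathing scales: 1 + amplitude * sin(2 pi (f-1) / period)
breathing_scales <- function(n_frames, period, amplitude) {
  1 + amplitude * sin(2 * pi * (seq_len(n_frames) - 1) / period)
}

# ground-truth stage labels from the sampled sine; one max-expansion and one
# min-contraction frame per complete cycle, earliest frame on ties
breathing_labels <- function(n_frames, period, amplitude) {
  labels <- rep("transitional", n_frames)
  if (amplitude <= 0) return(labels)
  sc <- breathing_scales(n_frames, period, amplitude)
  n_cycles <- n_frames %/% period
  for (cyc in seq_len(n_cycles)) {
    idx <- ((cyc - 1) * period + 1):(cyc * period)
    labels[idx[which.max(sc[idx])]] <- "max_expansion"
    labels[idx[which.min(sc[idx])]] <- "min_contraction"
  }
  labels
}

#' Generate a breathing-phantom acquisition
#'
#' Simulates the full gated acquisition: at every rotation angle a stack of
#' frames is recorded while the phantom "breathes" (its geometry scales by
#' `1 + amplitude * sin(2 pi (f-1) / period)` for frame `f`), with an
#' optional per-angle similarity jitter emulating subject drift, Fresnel
#' edge enhancement and Poisson noise. Ground truth (stage labels, jitter
#' transforms, per-stage true slices) is returned for validation.
#'
#' @param N Grid size (default 64).
#' @param geometry An [acquisition_geometry()]; its `n_angles`, `angle_step`
#'   and `frames_per_angle` define the sampling.
#' @param period Breathing period in frames (default 10). Not a measured
#'   quantity; exposed as a free parameter.
#' @param amplitude Peak fractional scale change of the slice (default
#'   0.04).
#' @param jitter `TRUE` for the default per-angle similarity perturbations
#'   (|rot| <= 2 deg, |t| <= 3 px, |s-1| <= 0.02), `FALSE`/`NULL` for none,
#'   or a list with elements `max_rot_deg`, `max_trans`, `max_scale`.
#' @param edge_enhance Apply Fresnel edge enhancement (default `TRUE`).
#' @param noise_photons Poisson flux per pixel, or `NULL` (noiseless).
#' @param phase_scale Radians of phase per unit line integral (default 0.01).
#' @param prop_distance Effective propagation distance for the edge
#'   enhancement; see [simulate_projection()].
#' @param base Optional base slice; default [chest_phantom()].
#' @param seed RNG seed (default 1); the whole acquisition is reproducible.
#' @return A list with `stacks` (per angle, an `N x N x frames` array),
#'   `angles` (degrees), `geometry`, and `truth`: `labels` (per-frame stage),
#'   `scales`, `stage_frames` (selected frame per stage), `jitter` (per-angle
#'   [similarity_transform()]), `slices` (true slice per stage), `envelope`,
#'   `slice_row` (the row of each frame that is the central slice's
#'   sinogram), `base`, `phase_scale`.
#' @export
make_breathing_phantom <- function(N = 64, geometry = NULL, period = 10,
                                   amplitude = 0.04, jitter = TRUE,
                                   edge_enhance = TRUE, noise_photons = NULL,
                                   phase_scale = 0.01, prop_distance = NULL,
                                   base = NULL, seed = 1) {
  if (N < 16) stop("N must be at least 16")
  if (period < 2) stop("period must be at least 2")
  if (is.null(geometry))
    geometry <- acquisition_geometry(n_angles = 180, angle_step = 1,
                                     frames_per_angle = 20)
  if (is.null(prop_distance))
    prop_distance <- (2.5 * geometry$pixel_pitch)^2 / geometry$wavelength
  Fn <- geometry$frames_per_angle
  if (Fn < period) stop("frames_per_angle must cover at least one period")
  if (is.null(base)) base <- chest_phantom(N)
  if (isTRUE(jitter)) jitter <- list(max_rot_deg = 2, max_trans = 3,
                                     max_scale = 0.02)
  angles <- geometry_angles(geometry)
  env <- phantom_envelope(N)
  scales <- breathing_scales(Fn, period, amplitude)
  labels <- breathing_labels(Fn, period, amplitude)
  bg <- if (edge_enhance) 1 else 0

  with_seed(seed, {
    jit <- vector("list", length(angles))
    for (a in seq_along(angles)) {
      jit[[a]] <- if (is.list(jitter) && a > 1) {
        similarity_transform(
          s = 1 + stats::runif(1, -jitter$max_scale, jitter$max_scale),
          theta = stats::runif(1, -jitter$max_rot_deg, jitter$max_rot_deg) *
            pi / 180,
          t = stats::runif(2, -jitter$max_trans, jitter$max_trans))
      } else similarity_transform()
    }
    uscales <- unique(scales)
    slices <- lapply(uscales, function(s) scale_slice(base, s))
    stacks <- vector("list", length(angles))
    for (a in seq_along(angles)) {
      stack <- array(0, dim = c(N, N, Fn))
      for (f in seq_len(Fn)) {
        sl <- slices[[match(scales[f], uscales)]]
        fr <- simulate_projection(sl, angles[a], geometry, envelope = env,
                                  edge_enhance = edge_enhance,
                                  phase_scale = phase_scale,
                                  prop_distance = prop_distance)
        if (is.list(jitter) && a > 1)
          fr <- warp(fr, jit[[a]], fill = bg)
        if (!is.null(noise_photons)) {
          cnt <- stats::rpois(length(fr), noise_photons * pmax(fr, 0))
          fr <- matrix(cnt / noise_photons, N, N)
        }
        stack[, , f] <- fr
      }
      stacks[[a]] <- stack
    }
    stage_frames <- list(
      max_expansion = lower_median(which(labels == "max_expansion")),
      min_contraction = lower_median(which(labels == "min_contraction")))
    true_slices <- lapply(stage_frames, function(f)
      if (length(f)) scale_slice(base, scales[f]) else base)
    list(stacks = stacks, angles = angles, geometry = geometry,
         truth = list(labels = labels, scales = scales,
                      stage_frames = stage_frames, jitter = jit,
                      slices = true_slices, envelope = env,
                      slice_row = N %/% 2 + 1, base = base,
                      phase_scale = phase_scale,
                      prop_distance = prop_distance))
  })
}

# box-average an (f*N) x (f*M) matrix down to N x M
box_downsample <- function(m, f) {
  N <- nrow(m) %/% f; M <- ncol(m) %/% f
  out <- matrix(0, N, M)
  for (di in seq_len(f)) for (dj in seq_len(f))
    out <- out + m[seq(di, by = f, length.out = N),
                   seq(dj, by = f, length.out = M)]
  out / f^2
}

# lower median: the floor((n+1)/2)-th order statistic (an actual element)
lower_median <- function(x) {
  if (!length(x)) return(integer(0))
  sort(x)[(length(x) + 1L) %/% 2L]
}

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
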