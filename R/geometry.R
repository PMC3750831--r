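#' Acquisition geometry for in-line phase-contrast CT
#'
#' Describes the synchrotron-style imaging geometry: a quasi-parallel beam,
#' a rotation stage between source and detector, and free-space propagation
#' over the object-to-detector distance that converts phase gradients into
#' edge-enhanced intensity contrast.
#'
#' @param R1 Source-to-object distance in metres (default 34 m).
#' @param R2 Object-to-detector distance in metres (default 1.2 m).
#' @param energy_keV Photon energy in keV; converted to wavelength unless
#'   `wavelength` is given directly. Default 25 keV.
#' @param wavelength Wavelength in metres; overrides `energy_keV`.
#' @param pixel_pitch Detector pixel size in metres (default 13e-6).
#' @param n_angles Number of rotation angles (default 180).
#' @param angle_step Angular step in degrees (default 1).
#' @param frames_per_angle Frames recorded at each angle (default 20),
#'   sampling several respiratory cycles.
#'
#' @return An object of class `acquisition_geometry`.
#' @details The effective propagation distance for a cone/spherical-wave
#'   set-up is `R2 * R1 / (R1 + R2)`; with `R1 >> R2` this is close to `R2`,
#'   the near-parallel synchrotron limit. Use [effective_distance()] to
#'   obtain it.
#' @export
#' @examples
#' g <- acquisition_geometry()
#' effective_distance(g)
acquisition_geometry <- function(R1 = 34, R2 = 1.2, energy_keV = 25,
                                 wavelength = NULL, pixel_pitch = 13e-6,
                                 n_angles = 180, angle_step = 1,
                                 frames_per_angle = 20) {
  if (is.null(wavelength)) {
    stopifnot(energy_keV > 0)
    wavelength <- kev_to_wavelength(energy_keV)
  }
  if (R1 <= 0) stop("R1 must be positive")
  if (R2 < 0) stop("R2 must be non-negative")
  if (wavelength <= 0) stop("wavelength must be positive")
  if (pixel_pitch <= 0) stop("pixel_pitch must be positive")
  if (n_angles < 1 || angle_step <= 0)
    stop("need n_angles >= 1 and angle_step > 0")
  if (n_angles * angle_step > 180 + angle_step)
    stop("angular range exceeds a half rotation (180 degrees)")
  structure(list(R1 = R1, R2 = R2, wavelength = wavelength,
                 pixel_pitch = pixel_pitch, n_angles = as.integer(n_angles),
                 angle_step = angle_step,
                 frames_per_angle = as.integer(frames_per_angle)),
            class = "acquisition_geometry")
}

#' Convert photon energy to wavelength
#'
#' @param energy_keV Photon energy in keV.
#' @return Wavelength in metres (`h*c / E`).
#' @export
kev_to_wavelength <- function(energy_keV) {
  1.23984193e-9 / energy_keV   # hc = 1.23984193 keV nm
}

#' Effective free-space propagation distance
#'
#' For a point source at distance `R1` upstream of the object and a detector
#' `R2` downstream, the Fresnel diffraction pattern equals that of plane-wave
#' illumination propagated over `R1 * R2 / (R1 + R2)` (up to magnification).
#'
#' @param geometry An [acquisition_geometry()].
#' @return Effective distance in metres.
#' @export
effective_distance <- function(geometry) {
  with(geometry, R1 * R2 / (R1 + R2))
}

#' Projection angles of a geometry
#' @param geometry An [acquisition_geometry()].
#' @return Numeric vector of angles in degrees, starting at 0.
#' @export
geometry_angles <- function(geometry) {
  (seq_len(geometry$n_angles) - 1) * geometry$angle_step
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf(
    "acquisition geometry: R1 = %g m, R2 = %g m, lambda = %.4g m\n",
    x$R1, x$R2, x$wavelength))
  cat(sprintf("  pixel pitch %g m; %d angles x %g deg; %d frames/angle\n",
              x$pixel_pitch, x$n_angles, x$angle_step, x$frames_per_angle))
  invisible(x)
}
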