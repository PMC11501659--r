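#' Gaussian beam specification
#'
#' Describes the freely diffracting illumination beam emitted by the delivery
#' fiber, propagating inside a homogeneous medium of refractive index `n`.
#' All lengths are in micrometres.
#'
#' @param waist_radius Beam waist radius \eqn{\omega_0} (µm).
#' @param wavelength Vacuum wavelength \eqn{\lambda_0} (µm).
#' @param medium_index Refractive index of the propagation medium (>= 1).
#' @param power Total beam power in arbitrary units (scales intensities).
#' @return An object of class `gaussian_beam`.
#' @examples
#' b <- gaussian_beam(4.2, 0.532, 1.46)
#' rayleigh_range(b)
#' @export
gaussian_beam <- function(waist_radius, wavelength, medium_index, power = 1) {
  stopifnot(is.numeric(waist_radius), is.numeric(wavelength),
            is.numeric(medium_index))
  if (waist_radius <= 0 || wavelength <= 0)
    stop("waist_radius and wavelength must be positive", call. = FALSE)
  if (medium_index < 1)
    stop("medium_index must be >= 1", call. = FALSE)
  structure(
    list(waist_radius = waist_radius, wavelength = wavelength,
         medium_index = medium_index, power = power),
    class = "gaussian_beam"
  )
}

#' @export
print.gaussian_beam <- function(x, ...) {
  cat(sprintf(
    "Gaussian beam: w0 = %g um, lambda0 = %g um, n = %g (z_R = %.1f um)\n",
    x$waist_radius, x$wavelength, x$medium_index, rayleigh_range(x)))
  invisible(x)
}

#' Rayleigh range of a Gaussian beam
#'
#' \eqn{z_R = \pi \omega_0^2 n / \lambda_0}: the axial distance over which
#' the beam cross-section doubles. Sets the scale on which the illumination
#' decays axially, and hence how far from the waist the measurement region
#' should sit for a flat field.
#'
#' @param beam A [gaussian_beam()].
#' @return Rayleigh range in µm.
#' @export
rayleigh_range <- function(beam) {
  stopifnot(inherits(beam, "gaussian_beam"))
  pi * beam$waist_radius^2 * beam$medium_index / beam$wavelength
}

#' Beam radius at axial position z
#'
#' \eqn{\omega(z) = \omega_0 \sqrt{1 + (z/z_R)^2}}.
#'
#' @inheritParams rayleigh_range
#' @param z Axial distance from the waist (µm); vectorized.
#' @return Beam radius (µm).
#' @export
beam_radius <- function(beam, z) {
  beam$waist_radius * sqrt(1 + (z / rayleigh_range(beam))^2)
}

#' Normalized Gaussian-beam intensity
#'
#' \eqn{I(r,z) = P\,[\omega_0/\omega(z)]^2 \exp(-2 r^2/\omega(z)^2)} with
#' I(0,0) = P (P = 1 by default, so intensities are normalized to the waist
#' center).
#'
#' @inheritParams rayleigh_range
#' @param r Radial offset from the beam axis (µm); vectorized.
#' @param z Axial distance from the waist (µm); vectorized.
#' @return Intensity (dimensionless, I(0,0) = power).
#' @export
beam_intensity <- function(beam, r, z) {
  w <- beam_radius(beam, z)
  beam$power * (beam$waist_radius / w)^2 * exp(-2 * r^2 / w^2)
}

#' Radial flatness across the channel
#'
#' Fractional intensity difference between channel center and channel edge at
#' axial position `z`: \eqn{1 - I(D/2, z)/I(0, z)}. Small values mean the
#' beam is wide enough that the channel sees an essentially flat transverse
#' profile.
#'
#' @inheritParams rayleigh_range
#' @param z Axial distance from the waist (µm), >= 0.
#' @param channel_diameter Microchannel diameter D (µm), >= 0.
#' @return Fractional center-to-edge difference in [0, 1).
#' @export
radial_flatness <- function(beam, z, channel_diameter) {
  if (any(channel_diameter < 0))
    stop("channel_diameter must be >= 0", call. = FALSE)
  if (any(z < 0)) stop("z must be >= 0", call. = FALSE)
  w <- beam_radius(beam, z)
  1 - exp(-2 * (channel_diameter / 2)^2 / w^2)
}

#' Axial intensity decay over a window
#'
#' Fractional on-axis intensity decrease between `z_a` and `z_a + dz`:
#' \eqn{1 - I(0, z_a + \Delta z)/I(0, z_a)}. Evaluated over one diffusion
#' length this quantifies how much illumination a particle loses by diffusing
#' down-beam during the measurement.
#'
#' @inheritParams rayleigh_range
#' @param z_a Start of the window, distance from the waist (µm), >= 0.
#' @param dz Window length (µm), >= 0.
#' @return Fractional decrease in [0, 1).
#' @export
axial_decay <- function(beam, z_a, dz) {
  if (any(z_a < 0) || any(dz < 0))
    stop("z_a and dz must be >= 0", call. = FALSE)
  zr <- rayleigh_range(beam)
  1 - (1 + (z_a / zr)^2) / (1 + ((z_a + dz) / zr)^2)
}

#' Classify the refractive-index-mismatch regime
#'
#' The sign of \eqn{\Delta n = n_{liquid} - n_{cladding}} determines how
#' light propagates in the liquid channel: `"guided"` (total internal
#' reflection concentrates light in the channel), `"leaky"` (power
#' dissipates transversely), or `"flat"` (index matched; the illumination
#' passes through unperturbed and the channel sees a flat field).
#'
#' @param delta_n Index mismatch \eqn{n_{mc} - n_{clad}}; vectorized.
#' @param tolerance Mismatch magnitude treated as matched (default 5e-5, an
#'   order of magnitude below the smallest mismatch of practical interest).
#' @return Character vector in {"guided", "leaky", "flat"}.
#' @examples
#' classify_regime(c(0.004, -0.004, 0))
#' @export
classify_regime <- function(delta_n, tolerance = 5e-5) {
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  ifelse(abs(delta_n) <= tolerance, "flat",
         ifelse(delta_n > 0, "guided", "leaky"))
}
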