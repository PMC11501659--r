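.kB <- 1.380649e-23 # J/K

#' Liquid specification
#'
#' @param refractive_index Refractive index of the liquid (dimensionless).
#' @param viscosity Dynamic viscosity (Pa s).
#' @param temperature Temperature (K).
#' @return Object of class `liquid_spec`.
#' @examples
#' dmso_water <- liquid_spec(1.4607, 3.3e-3, 293.15)
#' @export
liquid_spec <- function(refractive_index, viscosity, temperature) {
  if (viscosity <= 0 || temperature <= 0)
    stop("viscosity and temperature must be positive", call. = FALSE)
  structure(list(refractive_index = refractive_index, viscosity = viscosity,
                 temperature = temperature), class = "liquid_spec")
}

#' Particle specification
#'
#' The relative scattering scale defaults to the Rayleigh sixth-power law,
#' referenced to a 50 nm particle: \eqn{(d/d_{ref})^6}.
#'
#' @param diameter Particle diameter (nm).
#' @param material Free-text material tag.
#' @param scattering_scale Relative scattered-intensity scale; default
#'   `(diameter/reference_diameter)^6`.
#' @param reference_diameter Reference diameter for the default scale (nm).
#' @return Object of class `particle_spec`.
#' @export
particle_spec <- function(diameter, material = "gold",
                          scattering_scale = NULL,
                          reference_diameter = 50) {
  if (diameter <= 0) stop("diameter must be positive", call. = FALSE)
  if (is.null(scattering_scale))
    scattering_scale <- (diameter / reference_diameter)^6
  structure(list(diameter = diameter, material = material,
                 scattering_scale = scattering_scale),
            class = "particle_spec")
}

#' Stokes-Einstein diffusion coefficient
#'
#' \eqn{D = k_B T / (3 \pi \eta d)} for a sphere of diameter d in a fluid of
#' viscosity eta at temperature T.
#'
#' @param d Particle (hydrodynamic) diameter (nm).
#' @param eta Dynamic viscosity (Pa s).
#' @param temperature Temperature (K).
#' @return Diffusion coefficient (µm^2/s).
#' @examples
#' stokes_einstein_D(50, 3e-3, 293.15) # ~2.86 um^2/s
#' @export
stokes_einstein_D <- function(d, eta, temperature) {
  if (any(d <= 0) || any(eta <= 0) || any(temperature <= 0))
    stop("all inputs must be positive", call. = FALSE)
  .kB * temperature / (3 * pi * eta * d * 1e-9) * 1e12
}

#' Stokes-Einstein hydrodynamic diameter
#'
#' Exact algebraic inverse of [stokes_einstein_D()]:
#' \eqn{d_h = k_B T / (3 \pi \eta D)}.
#'
#' @param D Diffusion coefficient (µm^2/s).
#' @param eta Dynamic viscosity (Pa s).
#' @param temperature Temperature (K).
#' @return Hydrodynamic diameter (nm).
#' @examples
#' stokes_einstein_d(2.23, 3.3e-3, 293.15) # ~58.4 nm
#' @export
stokes_einstein_d <- function(D, eta, temperature) {
  if (any(D <= 0) || any(eta <= 0) || any(temperature <= 0))
    stop("all inputs must be positive", call. = FALSE)
  .kB * temperature / (3 * pi * eta * D * 1e-12) * 1e9
}

#' Diffusion length
#'
#' Root-mean-square 1D displacement \eqn{L = \sqrt{2 D \tau}} accumulated
#' over a measurement time tau; sets the axial window over which the
#' illumination must stay flat.
#'
#' @param D Diffusion coefficient (µm^2/s), >= 0.
#' @param tau Time (s), >= 0.
#' @return Length (µm).
#' @examples
#' diffusion_length(2.86, 65) # ~19 um
#' @export
diffusion_length <- function(D, tau) {
  if (any(D < 0) || any(tau < 0)) stop("D and tau must be >= 0", call. = FALSE)
  sqrt(2 * D * tau)
}

#' Hindrance factor for diffusion in a cylindrical channel
#'
#' Confinement slows diffusion relative to free solution; the hindrance
#' factor R >= 1 is the ratio of free to confined diffusion coefficient, so
#' the measured (hindered) D multiplied by R recovers the free-solution
#' value. The `"renkin"` model is the centerline Renkin / Paine-Scherr
#' polynomial \eqn{H(\lambda) = (1-\lambda)^2 (1 - 2.104\lambda +
#' 2.09\lambda^3 - 0.95\lambda^5)} with \eqn{\lambda = d / D_{mc}} and
#' \eqn{R = 1/H}; `"none"` returns 1 (free diffusion).
#'
#' @param d Particle diameter (nm).
#' @param channel_diameter Channel diameter (µm).
#' @param model `"renkin"` (default) or `"none"`.
#' @return Hindrance factor R >= 1.
#' @examples
#' hindrance_factor(50, 4) # ~1.05 for the 50 nm / 4 um geometry
#' @export
hindrance_factor <- function(d, channel_diameter, model = "renkin") {
  if (any(d < 0) || any(channel_diameter <= 0))
    stop("invalid geometry", call. = FALSE)
  lambda <- (d * 1e-3) / channel_diameter
  if (any(lambda >= 1))
    stop("particle does not fit in the channel", call. = FALSE)
  switch(model,
    renkin = {
      H <- (1 - lambda)^2 *
        (1 - 2.104 * lambda + 2.09 * lambda^3 - 0.95 * lambda^5)
      1 / H
    },
    none = rep(1, length(lambda)),
    stop("unknown hindrance model: ", model, call. = FALSE)
  )
}

#' Washburn capillary filling length
#'
#' Capillary-driven filling of a cylindrical channel:
#' \eqn{L(t) = \sqrt{\gamma R \cos\theta \, t / (2\eta)}}. Used to estimate
#' how long loading a capillary section by capillary action takes.
#'
#' @param surface_tension Liquid surface tension gamma (N/m).
#' @param contact_angle Contact angle theta (rad), < pi/2 for wetting.
#' @param channel_radius Channel radius R (µm).
#' @param eta Dynamic viscosity (Pa s).
#' @param t Time (s), >= 0; vectorized.
#' @return Filled length (µm).
#' @export
washburn_fill_length <- function(surface_tension, contact_angle,
                                 channel_radius, eta, t) {
  if (surface_tension <= 0 || channel_radius <= 0 || eta <= 0)
    stop("surface_tension, channel_radius and eta must be positive",
         call. = FALSE)
  if (contact_angle < 0 || contact_angle >= pi / 2)
    stop("contact_angle must be in [0, pi/2)", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  # SI internally, then back to um
  L_m <- sqrt(surface_tension * (channel_radius * 1e-6) * cos(contact_angle) *
                t / (2 * eta))
  L_m * 1e6
}

#' Washburn filling time for a given length
#'
#' Inverse of [washburn_fill_length()]: \eqn{t = 2 \eta L^2 /
#' (\gamma R \cos\theta)}.
#'
#' @inheritParams washburn_fill_length
#' @param length Target filled length (µm).
#' @return Time (s).
#' @export
washburn_fill_time <- function(surface_tension, contact_angle,
                               channel_radius, eta, length) {
  if (any(length < 0)) stop("length must be >= 0", call. = FALSE)
  2 * eta * (length * 1e-6)^2 /
    (surface_tension * (channel_radius * 1e-6) * cos(contact_angle))
}
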