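#' Channel geometry for the diffusion simulation
#'
#' @param radius Channel radius (µm), i.e. half the bore diameter.
#' @param axial_extent Modelled axial extent (µm); informational, the axial
#'   coordinate itself is unbounded.
#' @param axial_offset Distance of the channel entrance from the beam waist,
#'   z_a (µm). Illumination fields add this offset to trajectory z.
#' @return Object of class `channel_geometry`.
#' @examples
#' channel_geometry(radius = 2, axial_offset = 1000)
#' @export
channel_geometry <- function(radius, axial_extent = 210, axial_offset = 1000) {
  if (radius <= 0 || axial_extent <= 0)
    stop("radius and axial_extent must be positive", call. = FALSE)
  structure(list(radius = radius, axial_extent = axial_extent,
                 axial_offset = axial_offset), class = "channel_geometry")
}

#' Acquisition settings for the synthetic experiment
#'
#' Defaults are the reference study conditions: 1 kHz frame rate, 0.2 ms
#' exposure, 65,000 frames. Substeps subdivide the frame period; the first
#' `exposure * frame_rate` fraction of them falls inside the exposure window
#' and carries motion blur.
#'
#' @param frame_rate Frames per second (Hz).
#' @param exposure Exposure time per frame (s); must not exceed 1/frame_rate.
#' @param n_frames Number of frames, >= 1.
#' @param substeps Simulation substeps per frame period, >= 1 (default 10).
#' @param seed Integer RNG seed for reproducibility.
#' @return Object of class `acquisition_config`.
#' @export
acquisition_config <- function(frame_rate = 1000, exposure = 2e-4,
                               n_frames = 65000, substeps = 10, seed = 1) {
  if (exposure > 1 / frame_rate)
    stop("exposure must not exceed the frame period", call. = FALSE)
  if (n_frames < 1 || substeps < 1)
    stop("n_frames and substeps must be >= 1", call. = FALSE)
  structure(list(frame_rate = frame_rate, exposure = exposure,
                 n_frames = as.integer(n_frames),
                 substeps = as.integer(substeps),
                 seed = as.integer(seed)), class = "acquisition_config")
}

# substeps falling inside the exposure window (>= 1)
.exposure_substeps <- function(acq) {
  max(1L, as.integer(round(acq$substeps * acq$exposure * acq$frame_rate)))
}

#' Simulate confined Brownian motion in a cylindrical channel
#'
#' Free Brownian dynamics along the channel axis (z); transverse motion
#' (x, y) confined to the disc r <= radius by specular reflection of the
#' radial coordinate at the wall. Each substep of duration
#' 1/(frame_rate * substeps) increments every coordinate by a zero-mean
#' Gaussian step of standard deviation sqrt(2 D dt_sub). Deterministic given
#' the seed in `acq`.
#'
#' @param D Diffusion coefficient (µm^2/s), >= 0. Pass the *hindered* value
#'   if the confined channel mobility is to be emulated (see
#'   [hindrance_factor()]).
#' @param geometry A [channel_geometry()].
#' @param acq An [acquisition_config()].
#' @param start Optional c(x, y, z) start position (µm); default origin.
#' @return A `trajectory_record`: data.frame with one row per frame and
#'   columns `frame`, `t` (s), `x`, `y`, `z` (µm, instantaneous at frame
#'   start) and `x_exp`, `y_exp`, `z_exp` (averages over the exposure
#'   window, i.e. what a blur-integrating detector sees). The full
#'   substep-resolution path is attached as attribute `"substeps"` (matrix
#'   with columns x, y, z), along with `"geometry"`, `"acq"` and `"D"`.
#' @export
simulate_confined_brownian <- function(D, geometry, acq, start = c(0, 0, 0)) {
  stopifnot(inherits(geometry, "channel_geometry"),
            inherits(acq, "acquisition_config"))
  if (D < 0) stop("D must be >= 0", call. = FALSE)
  dt_sub <- 1 / (acq$frame_rate * acq$substeps)
  sigma <- sqrt(2 * D * dt_sub)
  if (sigma > geometry$radius / 5)
    stop("substep length exceeds radius/5; increase substeps", call. = FALSE)
  if (sqrt(start[1]^2 + start[2]^2) > geometry$radius)
    stop("start position outside the channel", call. = FALSE)
  n_sub <- acq$n_frames * acq$substeps
  set.seed(acq$seed)
  if (sigma > 0) {
    steps <- matrix(stats::rnorm(3 * n_sub, sd = sigma), ncol = 3)
  } else {
    steps <- matrix(0, nrow = n_sub, ncol = 3)
  }
  path <- cpp_reflect_walk(start[1], start[2], start[3],
                           steps[, 1], steps[, 2], steps[, 3],
                           geometry$radius)
  colnames(path) <- c("x", "y", "z")
  # positions: path[i, ] is the position after substep i; prepend the start
  full <- rbind(start, path)
  frame_start_idx <- seq(1, n_sub + 1 - acq$substeps, by = acq$substeps)
  n_exp <- .exposure_substeps(acq)
  exp_mean <- function(col) {
    acc <- full[frame_start_idx, col]
    for (k in seq_len(n_exp)) acc <- acc + full[frame_start_idx + k, col]
    acc / (n_exp + 1)
  }
  out <- data.frame(
    frame = seq_len(acq$n_frames),
    t = (seq_len(acq$n_frames) - 1) / acq$frame_rate,
    x = full[frame_start_idx, "x"],
    y = full[frame_start_idx, "y"],
    z = full[frame_start_idx, "z"],
    x_exp = exp_mean("x"), y_exp = exp_mean("y"), z_exp = exp_mean("z")
  )
  structure(out, substeps = path, geometry = geometry, acq = acq, D = D,
            class = c("trajectory_record", "data.frame"))
}

#' Illumination field
#'
#' Wraps an intensity function of channel coordinates (x, y transverse, z
#' axial along the channel, all µm). Constructors:
#' `illumination_gaussian_beam()` evaluates a [gaussian_beam()] at absolute
#' axial position `z_offset + z`; `illumination_radial()` takes a radial
#' profile f(r / radius) (z-invariant), useful for emulating guided
#' (center-peaked) or leaky (edge-peaked) mode profiles;
#' `illumination_uniform()` is constant.
#'
#' @param fun Function (x, y, z) -> intensity, vectorized.
#' @param label Short description.
#' @return Object of class `illumination_field`.
#' @export
illumination_field <- function(fun, label = "custom") {
  stopifnot(is.function(fun))
  structure(list(fun = fun, label = label), class = "illumination_field")
}

#' @rdname illumination_field
#' @param beam A [gaussian_beam()].
#' @param z_offset Distance of the channel entrance from the beam waist (µm).
#' @export
illumination_gaussian_beam <- function(beam, z_offset = 1000) {
  illumination_field(
    function(x, y, z) beam_intensity(beam, sqrt(x^2 + y^2), z_offset + z),
    label = "gaussian_beam")
}

#' @rdname illumination_field
#' @param profile Function of normalized radius u = r/radius in [0, 1].
#' @param radius Channel radius (µm).
#' @export
illumination_radial <- function(profile, radius) {
  illumination_field(
    function(x, y, z) profile(pmin(sqrt(x^2 + y^2) / radius, 1)),
    label = "radial")
}

#' @rdname illumination_field
#' @param level Constant intensity level.
#' @export
illumination_uniform <- function(level = 1) {
  illumination_field(function(x, y, z) rep(level, length(x)),
                     label = "uniform")
}

#' Scattered-intensity time series of a tracked particle
#'
#' Rayleigh point scatterer: per frame,
#' \eqn{I_s = s_d \, \bar I_{illum}} where \eqn{s_d} is the particle's
#' relative scattering scale (sixth-power in diameter by default) and
#' \eqn{\bar I_{illum}} averages the illumination over the substeps inside
#' the exposure window (motion blur).
#'
#' @param traj A `trajectory_record` from [simulate_confined_brownian()].
#' @param field An [illumination_field()].
#' @param particle A [particle_spec()].
#' @return Numeric vector, one intensity per frame (arbitrary units).
#' @export
scattered_intensity <- function(traj, field, particle) {
  stopifnot(inherits(traj, "trajectory_record"),
            inherits(field, "illumination_field"),
            inherits(particle, "particle_spec"))
  acq <- attr(traj, "acq")
  path <- attr(traj, "substeps")
  n_exp <- .exposure_substeps(acq)
  full_x <- c(traj$x[1], path[, "x"])
  full_y <- c(traj$y[1], path[, "y"])
  full_z <- c(traj$z[1], path[, "z"])
  idx0 <- seq(1, nrow(path) + 1 - acq$substeps, by = acq$substeps)
  acc <- field$fun(full_x[idx0], full_y[idx0], full_z[idx0])
  for (k in seq_len(n_exp))
    acc <- acc + field$fun(full_x[idx0 + k], full_y[idx0 + k],
                           full_z[idx0 + k])
  particle$scattering_scale * acc / (n_exp + 1)
}

#' Camera model
#'
#' 16-bit scientific camera defaults: noise floor 200 counts, saturation
#' 65,000 counts, pixel pitch 0.345 µm at the sample (3.45 µm sensor pixels
#' behind a 10x objective). `photon_scale` converts one unit of scattered
#' intensity into peak PSF counts; the default puts a 50 nm reference
#' particle under the reference illumination (Gaussian beam 1 mm from its
#' waist, relative intensity ~0.023) at ~20,000 counts peak, mid-range of
#' the 16-bit depth, so both noise floor and saturation remain relevant.
#'
#' @param pixel_pitch µm per pixel at the sample plane.
#' @param bit_depth Bits per pixel.
#' @param noise_floor Background offset I_min (counts).
#' @param saturation Saturation level I_max (counts); must satisfy
#'   0 < noise_floor < saturation <= 2^bit_depth - 1.
#' @param read_noise Gaussian read-noise sigma (counts).
#' @param photon_scale Peak counts per unit scattered intensity.
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(pixel_pitch = 0.345, bit_depth = 16,
                         noise_floor = 200, saturation = 65000,
                         read_noise = 5, photon_scale = 8.8e5) {
  if (!(noise_floor > 0 && noise_floor < saturation &&
        saturation <= 2^bit_depth - 1))
    stop("require 0 < noise_floor < saturation <= 2^bit_depth - 1",
         call. = FALSE)
  structure(list(pixel_pitch = pixel_pitch, bit_depth = as.integer(bit_depth),
                 noise_floor = noise_floor, saturation = saturation,
                 read_noise = read_noise, photon_scale = photon_scale),
            class = "camera_model")
}

# Deterministic moving axial render window: returns, per frame, the window
# origin (µm of the first pixel column) such that the particle stays at
# least `margin` px from either edge; the window recenters when violated.
.window_origins <- function(z_um, pitch, nz, margin) {
  origin <- numeric(length(z_um))
  cur <- z_um[1] - (nz / 2) * pitch
  for (i in seq_along(z_um)) {
    zp <- (z_um[i] - cur) / pitch
    if (zp < margin || zp > nz - 1 - margin)
      cur <- z_um[i] - (nz / 2) * pitch
    origin[i] <- cur
  }
  origin
}

#' Render synthetic camera frames
#'
#' Projects the trajectory onto the (x, z) image plane and renders each
#' frame as the exposure-substep sum of diffraction-limited Airy patterns
#' (first zero at 0.61 lambda / NA), scaled by the scattered-intensity
#' series and the camera photon scale, then applies Poisson shot noise,
#' Gaussian read noise, the noise-floor offset, integer quantization and
#' clipping at saturation. Depth (y) defocus is ignored (objective depth of
#' field exceeds the channel bore). The axial field of view follows the
#' particle as a moving window; ground truth keeps absolute z.
#'
#' @param traj A `trajectory_record`.
#' @param intensities Per-frame scattered intensities
#'   ([scattered_intensity()]).
#' @param camera A [camera_model()].
#' @param na Numerical aperture of the imaging objective.
#' @param wavelength Imaging wavelength (µm).
#' @param fov c(nx, nz) image size in pixels (transverse, axial).
#' @param noise Apply the stochastic noise model (default TRUE).
#' @param seed RNG seed for the noise draws (default: acquisition seed + 1).
#' @param frames Optional integer vector of frame indices to render (for
#'   chunked processing); default all.
#' @return A `frame_stack`: list with `frames` (integer array nx x nz x
#'   nframes), `origin_z_um` (axial window origin per frame), `pixel_pitch`,
#'   `frame_index`, `times`, and the camera/optics metadata.
#' @export
render_frames <- function(traj, intensities, camera, na = 0.25,
                          wavelength = 0.532, fov = c(30, 600),
                          noise = TRUE, seed = NULL, frames = NULL) {
  stopifnot(inherits(traj, "trajectory_record"),
            inherits(camera, "camera_model"),
            length(intensities) == nrow(traj))
  acq <- attr(traj, "acq")
  pitch <- camera$pixel_pitch
  r0_um <- 0.61 * wavelength / na # first Airy zero
  r0_px <- r0_um / pitch
  if (r0_px < 1)
    stop("PSF radius under 1 px: undersampled imaging configuration",
         call. = FALSE)
  nx <- as.integer(fov[1]); nz <- as.integer(fov[2])
  stamp_radius <- 2.6 * r0_px # covers the first two Airy rings
  margin <- ceiling(stamp_radius) + 2
  if (nz <= 2 * margin)
    stop("axial field of view too small for the PSF stamp", call. = FALSE)
  origins <- .window_origins(traj$z_exp, pitch, nz, margin)
  if (is.null(frames)) frames <- seq_len(nrow(traj))
  path <- attr(traj, "substeps")
  full_x <- c(traj$x[1], path[, "x"])
  full_z <- c(traj$z[1], path[, "z"])
  n_exp <- .exposure_substeps(acq)
  idx0 <- (frames - 1) * acq$substeps + 1
  # substep positions within each rendered frame's exposure (incl. start)
  sub_idx <- as.vector(t(outer(idx0, 0:n_exp, `+`)))
  frame_of <- rep(seq_along(frames), each = n_exp + 1)
  x_um <- full_x[sub_idx]
  z_um <- full_z[sub_idx]
  x_px <- x_um / pitch + (nx - 1) / 2
  if (any(x_px < 0 | x_px > nx - 1))
    stop("particle leaves the transverse field of view", call. = FALSE)
  z_px <- (z_um - origins[frames][frame_of]) / pitch
  weight <- camera$photon_scale * intensities[frames][frame_of] / (n_exp + 1)
  v_per_px <- 2 * pi / wavelength * na * pitch
  if (is.null(seed)) seed <- acq$seed + 1L
  set.seed(seed)
  raw <- cpp_render_frames(as.integer(frame_of), x_px, z_px, weight,
                           nx, nz, length(frames), v_per_px, stamp_radius,
                           camera$noise_floor, camera$read_noise,
                           camera$saturation, isTRUE(noise))
  structure(list(
    frames = array(raw, dim = c(nx, nz, length(frames))),
    origin_z_um = origins[frames],
    pixel_pitch = pitch,
    frame_index = frames,
    times = traj$t[frames],
    camera = camera, na = na, wavelength = wavelength
  ), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d frames of %d x %d px (pitch %g um/px)\n",
              d[3], d[1], d[2], x$pixel_pitch))
  invisible(x)
}

#' Write a frame stack as a multi-page 16-bit TIFF
#'
#' @param stack A `frame_stack` from [render_frames()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(stack, path) {
  d <- dim(stack$frames)
  pages <- lapply(seq_len(d[3]), function(i)
    stack$frames[, , i] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a ground-truth trajectory (and intensity series) as CSV
#'
#' @param traj A `trajectory_record`.
#' @param path Output file path.
#' @param intensities Optional per-frame true scattered intensities, written
#'   as column `I_true`.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, intensities = NULL) {
  df <- as.data.frame(traj)
  if (!is.null(intensities)) df$I_true <- intensities
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
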