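#' Default run configuration
#'
#' Nested configuration for a full synthetic CaNTA run, mirroring the
#' reference study conditions: a 50 nm gold nanosphere in a water/DMSO
#' mixture (n = 1.4607, eta = 3.3 mPa s, T = 293.15 K) inside a 4 µm silica
#' capillary bore, illuminated at 532 nm by a Gaussian beam (waist 4.2 µm)
#' launched 1 mm before the channel, imaged at 1 kHz / 0.2 ms exposure on a
#' 16-bit camera for 65,000 frames. Configurations are plain nested lists
#' and round-trip losslessly through YAML ([read_run_config()] /
#' [write_run_config()]).
#'
#' @return Nested list with sections `optics`, `capillary`, `liquid`,
#'   `particle`, `acquisition`, `camera`, `tracking`, `bins`, `msd`, `seed`.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    optics = list(waist_radius = 4.2, wavelength = 0.532,
                  medium_index = 1.4607, axial_offset = 1000, na = 0.25),
    capillary = list(channel_diameter = 4, outer_diameter = 125,
                     cladding_index = 1.4607),
    liquid = list(refractive_index = 1.4607, viscosity = 3.3e-3,
                  temperature = 293.15),
    particle = list(diameter = 50, material = "gold"),
    acquisition = list(frame_rate = 1000, exposure = 2e-4,
                       n_frames = 65000L, substeps = 10L),
    camera = list(pixel_pitch = 0.345, bit_depth = 16L, noise_floor = 200,
                  saturation = 65000, read_noise = 5, photon_scale = 8.8e5),
    tracking = list(spot_diameter = 15, search_radius = 5, memory = 1L),
    bins = list(),  # empty -> thirds of the channel width
    msd = list(n_lags = 2L, max_lag = 10L, n_blocks = 20L),
    measurement_time = 65
  )
}

#' Read / write a run configuration (YAML)
#'
#' @param path File path.
#' @return For `read_run_config`, the configuration list (missing sections
#'   filled from [default_config()]).
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (sec in names(user)) {
    if (is.list(user[[sec]]) && is.list(cfg[[sec]])) {
      for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
    } else {
      cfg[[sec]] <- user[[sec]]
    }
  }
  validate_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param config Configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Validate a run configuration
#'
#' Checks presence and basic sanity of every referenced section; errors
#' list all offending keys at once.
#'
#' @param config Configuration list.
#' @return `config`, invisibly, or an error.
#' @export
validate_config <- function(config) {
  bad <- character(0)
  need <- function(cond, key) if (!isTRUE(cond)) bad <<- c(bad, key)
  need(config$optics$waist_radius > 0, "optics.waist_radius")
  need(config$optics$wavelength > 0, "optics.wavelength")
  need(config$optics$medium_index >= 1, "optics.medium_index")
  need(config$capillary$channel_diameter > 0 &&
         config$capillary$channel_diameter < config$capillary$outer_diameter,
       "capillary.channel_diameter")
  need(config$liquid$viscosity > 0, "liquid.viscosity")
  need(config$liquid$temperature > 0, "liquid.temperature")
  need(config$particle$diameter > 0, "particle.diameter")
  need(config$acquisition$n_frames >= 1, "acquisition.n_frames")
  need(config$acquisition$exposure <= 1 / config$acquisition$frame_rate,
       "acquisition.exposure")
  need(config$camera$noise_floor > 0 &&
         config$camera$noise_floor < config$camera$saturation,
       "camera.noise_floor")
  if (length(bad) > 0)
    stop("invalid config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(config)
}

#' Flat-field design report
#'
#' Evaluates the closed-form design calculus for a configuration: Rayleigh
#' range, beam radius at the channel entrance, radial flatness across the
#' bore, Stokes-Einstein diffusion coefficient and diffusion length of the
#' configured particle, the axial intensity decay over that length, the
#' index-mismatch regime, and the camera dynamic range.
#'
#' @param config Configuration list (see [default_config()]).
#' @return Named list of design metrics (a JSON-ready report).
#' @examples
#' run_design(default_config())
#' @export
run_design <- function(config = default_config()) {
  validate_config(config)
  beam <- gaussian_beam(config$optics$waist_radius, config$optics$wavelength,
                        config$optics$medium_index)
  z_a <- config$optics$axial_offset
  D_dif <- stokes_einstein_D(config$particle$diameter,
                             config$liquid$viscosity,
                             config$liquid$temperature)
  tau_m <- if (!is.null(config$measurement_time)) config$measurement_time
           else config$acquisition$n_frames / config$acquisition$frame_rate
  L_dif <- diffusion_length(D_dif, tau_m)
  dn <- config$liquid$refractive_index - config$capillary$cladding_index
  list(
    rayleigh_range_um = rayleigh_range(beam),
    beam_radius_at_za_um = beam_radius(beam, z_a),
    radial_flatness_pct = 100 * radial_flatness(
      beam, z_a, config$capillary$channel_diameter),
    axial_decay_pct = 100 * axial_decay(beam, z_a, L_dif),
    D_dif_um2_s = D_dif,
    L_dif_um = L_dif,
    delta_n = dn,
    regime = classify_regime(dn),
    hindrance_factor = hindrance_factor(config$particle$diameter,
                                        config$capillary$channel_diameter),
    dynamic_range = dynamic_range(config$camera$noise_floor,
                                  config$camera$saturation)
  )
}

#' Run the full synthetic pipeline
#'
#' Simulate -> render -> track -> flat-field statistics -> MSD sizing, all
#' driven by one configuration and one seed. The generator simulates the
#' *hindered* axial diffusion (free Stokes-Einstein D divided by the Renkin
#' hindrance factor of the configured geometry), and the sizing step applies
#' the same factor, so the reported hydrodynamic diameter estimates the
#' configured free-solution diameter. Rendering and tracking run in chunks
#' so the full image stack is never held in memory.
#'
#' @param config Configuration list.
#' @param seed Overall seed; overrides `config$seed` if given.
#' @param fov Rendered field of view c(nx, nz) in px (default c(30, 200); a
#'   moving axial window follows the particle).
#' @param chunk Frames per render/track chunk.
#' @param out_dir Optional directory; if given, the ground-truth trajectory,
#'   linked track, flat-field report and MSD results are written there
#'   (CSV/JSON).
#' @param verbose Log stage progress to stderr.
#' @return A `run_report` list: config echo, package version, per-stage
#'   summaries (`design`, `tracking`, `flatfield`, `msd`) and wall-clock
#'   seconds per stage.
#' @export
run_full <- function(config = default_config(), seed = NULL,
                     fov = c(30, 200), chunk = 5000, out_dir = NULL,
                     verbose = TRUE) {
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  say <- function(stage, ...) if (verbose)
    message(sprintf("[canta:%s] ", stage), sprintf(...))
  timing <- list()
  clock <- function(expr, stage) {
    t0 <- proc.time()[3]
    v <- force(expr)
    timing[[stage]] <<- unname(proc.time()[3] - t0)
    v
  }
  say("design", "seed = %d", config$seed)
  design <- clock(run_design(config), "design")

  ## --- simulate -------------------------------------------------------
  R_h <- design$hindrance_factor
  D_sim <- design$D_dif_um2_s / R_h
  geom <- channel_geometry(radius = config$capillary$channel_diameter / 2,
                           axial_offset = config$optics$axial_offset)
  acq <- acquisition_config(config$acquisition$frame_rate,
                            config$acquisition$exposure,
                            config$acquisition$n_frames,
                            config$acquisition$substeps,
                            seed = config$seed)
  say("simulate", "N = %d frames, D_sim = %.3f um2/s (hindered)",
      acq$n_frames, D_sim)
  traj <- clock(simulate_confined_brownian(D_sim, geom, acq), "simulate")
  beam <- gaussian_beam(config$optics$waist_radius, config$optics$wavelength,
                        config$optics$medium_index)
  field <- illumination_gaussian_beam(beam, config$optics$axial_offset)
  particle <- particle_spec(config$particle$diameter,
                            config$particle$material)
  intens <- scattered_intensity(traj, field, particle)

  ## --- render + track (chunked) --------------------------------------
  camera <- do.call(camera_model, config$camera)
  tcfg <- tracking_config(spot_diameter = config$tracking$spot_diameter,
                          search_radius = config$tracking$search_radius,
                          memory = config$tracking$memory)
  say("track", "rendering/tracking %d frames in chunks of %d",
      acq$n_frames, chunk)
  t0 <- proc.time()[3]
  det_list <- list()
  starts <- seq(1, acq$n_frames, by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1, acq$n_frames)
    stack <- render_frames(traj, intens, camera, na = config$optics$na,
                           wavelength = config$optics$wavelength,
                           fov = fov, seed = config$seed + 1L + s,
                           frames = idx)
    det_list[[length(det_list) + 1]] <- locate_stack(stack, tcfg)
  }
  detections <- do.call(rbind, det_list)
  track <- link_trajectories(detections, tcfg, camera$pixel_pitch)
  # keep the dominant track
  main_id <- as.integer(names(which.max(table(track$track_id))))
  track <- track[track$track_id == main_id, ]
  timing$track <- unname(proc.time()[3] - t0)
  say("track", "%d/%d frames recovered in the main track",
      nrow(track), acq$n_frames)

  ## --- flat-field statistics ------------------------------------------
  scheme <- if (length(config$bins) == 0)
    bin_scheme(config$capillary$channel_diameter)
  else bin_scheme(config$capillary$channel_diameter,
                  cb = config$bins$cb, sb = config$bins$sb)
  ff <- clock({
    norm_i <- normalize_intensity(track$mass)
    labels <- assign_bins(track$x_um, scheme)
    fit_cb <- fit_intensity_histogram(norm_i[labels == "CB"])
    fit_sb <- fit_intensity_histogram(norm_i[labels == "SB"])
    flatfield_metrics(fit_cb, fit_sb, norm_i)
  }, "flatfield")
  say("flatfield", "dI_max = %+.3f %%, dI = %.2f %%",
      ff$delta_imax_pct, ff$delta_i_pct)

  ## --- MSD sizing ------------------------------------------------------
  liquid <- liquid_spec(config$liquid$refractive_index,
                        config$liquid$viscosity,
                        config$liquid$temperature)
  msd_out <- clock({
    dt <- 1 / acq$frame_rate
    m <- compute_msd(track$z_um, dt, max_lag = config$msd$max_lag)
    fit <- fit_diffusion(m, n_lags = config$msd$n_lags)
    unc <- d_uncertainty(track$z_um, dt, n_blocks = config$msd$n_blocks,
                         n_lags = config$msd$n_lags, liquid = liquid,
                         hindrance = R_h)
    list(msd = as.data.frame(m), D = fit$D, intercept = fit$intercept,
         se_D = unc$se_D, d_h = unc$d_h, se_d = unc$se_d,
         hindrance_factor = R_h)
  }, "msd")
  say("msd", "D = %.3f +/- %.3f um2/s, d_h = %.1f +/- %.1f nm",
      msd_out$D, msd_out$se_D, msd_out$d_h, msd_out$se_d)

  report <- list(
    package_version = as.character(utils::packageVersion("canta")),
    seed = config$seed,
    config = config,
    design = design,
    tracking = list(n_frames = acq$n_frames, n_tracked = nrow(track),
                    coverage = nrow(track) / acq$n_frames),
    flatfield = unclass(ff),
    msd = msd_out,
    timing_s = timing
  )
  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trajectory_csv(traj, file.path(out_dir, "truth_trajectory.csv"),
                         intensities = intens)
    utils::write.csv(track, file.path(out_dir, "track.csv"),
                     row.names = FALSE)
    utils::write.csv(msd_out$msd, file.path(out_dir, "msd.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report[setdiff(names(report), "msd")],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("CaNTA run (seed %d): %d frames, coverage %.1f %%\n",
              x$seed, x$tracking$n_frames, 100 * x$tracking$coverage))
  cat(sprintf("  design : regime %s, flatness %.2f %%, decay %.2f %%\n",
              x$design$regime, x$design$radial_flatness_pct,
              x$design$axial_decay_pct))
  cat(sprintf("  flat   : dI_max %+.3f %%, dI %.2f %%\n",
              x$flatfield$delta_imax_pct, x$flatfield$delta_i_pct))
  cat(sprintf("  sizing : D = %.3f +/- %.3f um2/s, d_h = %.1f +/- %.1f nm\n",
              x$msd$D, x$msd$se_D, x$msd$d_h, x$msd$se_d))
  invisible(x)
}
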