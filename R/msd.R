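#' Mean squared displacement of a 1D trajectory
#'
#' For each lag k = 1..max_lag, averages the squared axial position
#' differences over all overlapping pairs of the trajectory:
#' \eqn{MSD(k\Delta t) = \langle (z_{i+k} - z_i)^2 \rangle}. The shortest
#' lag averages N - 1 values and carries the highest statistical weight.
#' Axial-only (1D) displacements are used: transverse motion is confined by
#' the channel and would bias a multi-dimensional MSD.
#'
#' @param z Axial positions (µm), or a data.frame with a `z_um` (or `z`)
#'   column such as a linked trajectory.
#' @param dt Frame interval (s).
#' @param max_lag Largest lag in frames (default 10); must be < length(z).
#' @return Object of class `msd_result`: data.frame with `lag_frames`,
#'   `lag_s`, `msd` (µm^2) and `n_pairs`, with `dt` as an attribute.
#' @export
compute_msd <- function(z, dt, max_lag = 10) {
  if (is.data.frame(z)) z <- if ("z_um" %in% names(z)) z$z_um else z$z
  n <- length(z)
  if (max_lag >= n)
    stop("max_lag must be smaller than the trajectory length", call. = FALSE)
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(k) mean(diff(z, lag = k)^2), 0)
  out <- data.frame(lag_frames = lags, lag_s = lags * dt, msd = msd,
                    n_pairs = n - lags)
  structure(out, dt = dt, class = c("msd_result", "data.frame"))
}

#' Diffusion coefficient from the first MSD lags
#'
#' Ordinary least-squares line through the first `n_lags` (lag time, MSD)
#' points; for 1D diffusion the slope is 2D. The intercept is reported as a
#' diagnostic: static localization error shifts it up, motion blur shifts it
#' down, and on clean data it is ~0. The first two lags carry the greatest
#' statistical significance; using many lags typically reduces accuracy, so
#' a warning is issued above 4.
#'
#' @param msd An `msd_result` from [compute_msd()].
#' @param n_lags Number of leading lags to fit (>= 2, default 2).
#' @return List with `D` (µm^2/s), `slope`, `intercept` (µm^2) and `n_lags`.
#' @export
fit_diffusion <- function(msd, n_lags = 2) {
  stopifnot(inherits(msd, "msd_result"))
  if (n_lags < 2) stop("n_lags must be >= 2", call. = FALSE)
  if (n_lags > nrow(msd))
    stop("n_lags exceeds available lags", call. = FALSE)
  if (n_lags > 4)
    warning("fitting more than 4 lag times typically reduces accuracy")
  d <- msd[seq_len(n_lags), ]
  fit <- stats::lm(msd ~ lag_s, data = d)
  slope <- unname(stats::coef(fit)[2])
  if (slope < 0)
    stop("negative MSD slope: trajectory does not look diffusive ",
         "(tracking failure?)", call. = FALSE)
  list(D = slope / 2, slope = slope,
       intercept = unname(stats::coef(fit)[1]), n_lags = n_lags)
}

#' Hydrodynamic diameter from a measured diffusion coefficient
#'
#' Inverts the Stokes-Einstein relation after correcting the measured
#' (hindered) diffusion coefficient for confinement:
#' \eqn{d_h = k_B T / (3 \pi \eta \, (D \cdot R))}, where R >= 1 is the
#' hindrance factor. With R = 1 this is exactly
#' [stokes_einstein_d()].
#'
#' @param D Measured diffusion coefficient (µm^2/s), > 0.
#' @param liquid A [liquid_spec()].
#' @param hindrance Hindrance factor R (default 1; see
#'   [hindrance_factor()]).
#' @return Hydrodynamic diameter (nm).
#' @export
size_particle <- function(D, liquid, hindrance = 1) {
  stopifnot(inherits(liquid, "liquid_spec"))
  stokes_einstein_d(D * hindrance, liquid$viscosity, liquid$temperature)
}

#' Block-bootstrap uncertainty of D and the hydrodynamic diameter
#'
#' Splits the trajectory into `n_blocks` non-overlapping segments, estimates
#' D independently on each (first-`n_lags` MSD fit), and reports the
#' standard error of the full-trajectory estimate as
#' sd(blocks)/sqrt(n_blocks). Propagated to the diameter to first order:
#' \eqn{\sigma_d / d = \sigma_D / D}. The block standard error inherits the
#' \eqn{\sigma_D \propto 1/\sqrt{N}} scaling of the underlying estimator.
#'
#' @param z Axial positions (µm) or a trajectory data.frame.
#' @param dt Frame interval (s).
#' @param n_blocks Number of non-overlapping blocks (default 20).
#' @param n_lags Lags for the per-block fit (default 2).
#' @param liquid Optional [liquid_spec()]; if given, the diameter and its
#'   standard error are included.
#' @param hindrance Hindrance factor for the sizing step.
#' @return List with `D`, `se_D`, `n_blocks`, and (with `liquid`) `d_h`,
#'   `se_d`.
#' @export
d_uncertainty <- function(z, dt, n_blocks = 20, n_lags = 2,
                          liquid = NULL, hindrance = 1) {
  if (is.data.frame(z)) z <- if ("z_um" %in% names(z)) z$z_um else z$z
  n <- length(z)
  if (n < 100) stop("trajectory too short (need >= 100 frames)", call. = FALSE)
  block_len <- n %/% n_blocks
  if (block_len < 10 * n_lags)
    stop("too few frames per block; reduce n_blocks", call. = FALSE)
  D_blocks <- vapply(seq_len(n_blocks), function(b) {
    seg <- z[((b - 1) * block_len + 1):(b * block_len)]
    fit_diffusion(compute_msd(seg, dt, max_lag = n_lags), n_lags)$D
  }, 0)
  D_full <- fit_diffusion(compute_msd(z, dt, max_lag = n_lags), n_lags)$D
  se_D <- stats::sd(D_blocks) / sqrt(n_blocks)
  out <- list(D = D_full, se_D = se_D, n_blocks = n_blocks)
  if (!is.null(liquid)) {
    d_h <- size_particle(D_full, liquid, hindrance)
    out$d_h <- d_h
    out$se_d <- d_h * se_D / D_full
  }
  out
}
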