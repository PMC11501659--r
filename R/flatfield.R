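#' Transverse bin scheme for flat-field verification
#'
#' Divides the channel cross-section by transverse position x into a central
#' bin (CB, symmetric about the channel axis) and two flanking side bins
#' (SBs). Default: thirds of the channel width. Intervals are half-open
#' [lo, hi) so boundary assignment is deterministic.
#'
#' @param channel_diameter Channel diameter (µm).
#' @param cb Central-bin interval c(lo, hi) (µm); default the middle third.
#' @param sb List of two side-bin intervals; default the outer thirds.
#' @return Object of class `bin_scheme`.
#' @examples
#' bin_scheme(4)
#' @export
bin_scheme <- function(channel_diameter, cb = NULL, sb = NULL) {
  if (channel_diameter <= 0)
    stop("channel_diameter must be positive", call. = FALSE)
  h <- channel_diameter / 2
  if (is.null(cb)) cb <- c(-h / 3, h / 3)
  if (is.null(sb)) sb <- list(c(-h, -h / 3), c(h / 3, h))
  ivs <- c(list(cb), sb)
  for (iv in ivs) {
    if (length(iv) != 2 || iv[1] >= iv[2])
      stop("bin intervals must be c(lo, hi) with lo < hi", call. = FALSE)
    if (iv[1] < -h - 1e-9 || iv[2] > h + 1e-9)
      stop("bin intervals must lie within the channel", call. = FALSE)
  }
  srt <- ivs[order(vapply(ivs, `[`, 0, 1))]
  for (i in seq_len(length(srt) - 1))
    if (srt[[i]][2] > srt[[i + 1]][1] + 1e-12)
      stop("bin intervals overlap", call. = FALSE)
  structure(list(cb = cb, sb = sb, channel_diameter = channel_diameter),
            class = "bin_scheme")
}

#' Assign trajectory frames to transverse bins
#'
#' Labels each frame by the half-open interval [lo, hi) containing its
#' transverse position; positions outside all intervals get `"none"`.
#'
#' @param x Transverse positions (µm, channel coordinates), or a data.frame
#'   with an `x_um` (or `x`) column.
#' @param scheme A [bin_scheme()].
#' @return Factor with levels CB, SB, none.
#' @export
assign_bins <- function(x, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  if (is.data.frame(x)) x <- if ("x_um" %in% names(x)) x$x_um else x$x
  lab <- rep("none", length(x))
  lab[x >= scheme$cb[1] & x < scheme$cb[2]] <- "CB"
  for (iv in scheme$sb) lab[x >= iv[1] & x < iv[2]] <- "SB"
  factor(lab, levels = c("CB", "SB", "none"))
}

#' Expected bin occupancy for uniform transverse positions
#'
#' For a particle whose transverse position is uniform over the channel disc
#' of radius R, the probability of x falling in [a, b] is the chord-weighted
#' area \eqn{\int_a^b 2\sqrt{R^2-x^2}\,dx / (\pi R^2)}. Used as a
#' closed-form check on [assign_bins()] counts.
#'
#' @param scheme A [bin_scheme()].
#' @return Named vector of probabilities for CB and SB.
#' @export
bin_occupancy_uniform_disc <- function(scheme) {
  R <- scheme$channel_diameter / 2
  seg <- function(a, b) {
    f <- function(x) x * sqrt(pmax(R^2 - x^2, 0)) + R^2 * asin(pmin(pmax(x / R, -1), 1))
    (f(b) - f(a)) / (pi * R^2)
  }
  cb <- seg(scheme$cb[1], scheme$cb[2])
  sb <- sum(vapply(scheme$sb, function(iv) seg(iv[1], iv[2]), 0))
  c(CB = cb, SB = sb)
}

#' Fit a Gaussian to an intensity histogram
#'
#' Bins the (normalized) intensity values into an occurrence-probability
#' histogram (Freedman-Diaconis width by default) and fits
#' \eqn{A \exp(-(I-\mu)^2 / 2\sigma^2)} by nonlinear least squares,
#' initialized from the sample mean and standard deviation.
#'
#' @param values Numeric vector of intensities, length >= 100.
#' @param breaks Passed to [graphics::hist()] binning (default `"FD"`).
#' @return Object of class `gaussian_fit`: list with `mu`, `sigma`,
#'   `amplitude`, `fwhm` (= 2 sqrt(2 ln 2) sigma), `n`, and the histogram
#'   (`mids`, `prob`).
#' @export
fit_intensity_histogram <- function(values, breaks = "FD") {
  if (length(values) < 100)
    stop("need at least 100 values for a stable fit", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("degenerate (constant) intensity data", call. = FALSE)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  prob <- h$counts / sum(h$counts)
  df <- data.frame(x = h$mids, p = prob)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      p ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
      start = list(A = max(prob), mu = mean(values), s = stats::sd(values)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Gaussian fit did not converge: ", conditionMessage(e),
           call. = FALSE))
  cf <- stats::coef(fit)
  s <- abs(unname(cf["s"]))
  if (s <= 0) stop("Gaussian fit degenerate (sigma <= 0)", call. = FALSE)
  structure(list(mu = unname(cf["mu"]), sigma = s,
                 amplitude = unname(cf["A"]),
                 fwhm = 2 * sqrt(2 * log(2)) * s,
                 n = length(values),
                 histogram = df),
            class = "gaussian_fit")
}

#' Flat-field verification metrics
#'
#' Compares the Gaussian-fit peak intensities of the central and side bins.
#' All intensities are renormalized by the CB fit peak
#' (\eqn{I \to I / \mu_{CB}}), then the peak intensity difference is
#' \eqn{\delta I_{max} = 100 (\mu_{CB} - \mu_{SB}) / \mu_{CB}} (percent;
#' positive when the channel center is brighter, as for guided-mode
#' illumination; negative when the sides are brighter, as for leaky
#' illumination; near zero for a flat field). Also reports the relative
#' standard deviation of the full series \eqn{\delta I = 100 \sigma_I /
#' \bar I}, the per-bin FWHMs, sample counts, and the full-series skewness
#' as a symmetry diagnostic.
#'
#' @param fit_cb,fit_sb `gaussian_fit` objects for the central / side bins.
#' @param full_series Optional full normalized intensity series for the
#'   delta-I and symmetry diagnostics.
#' @return Object of class `flatfield_report`.
#' @export
flatfield_metrics <- function(fit_cb, fit_sb, full_series = NULL) {
  stopifnot(inherits(fit_cb, "gaussian_fit"), inherits(fit_sb, "gaussian_fit"))
  if (fit_cb$mu <= 0)
    stop("CB peak intensity must be positive", call. = FALSE)
  delta_imax <- 100 * (fit_cb$mu - fit_sb$mu) / fit_cb$mu
  rel_sd <- skew <- NA_real_
  if (!is.null(full_series)) {
    rel_sd <- 100 * stats::sd(full_series) / mean(full_series)
    m <- mean(full_series)
    s <- stats::sd(full_series)
    skew <- mean((full_series - m)^3) / s^3
  }
  structure(list(
    delta_imax_pct = delta_imax,
    delta_i_pct = rel_sd,
    skewness = skew,
    mu_cb = fit_cb$mu / fit_cb$mu, mu_sb = fit_sb$mu / fit_cb$mu,
    fwhm_cb = fit_cb$fwhm / fit_cb$mu, fwhm_sb = fit_sb$fwhm / fit_cb$mu,
    n_cb = fit_cb$n, n_sb = fit_sb$n
  ), class = "flatfield_report")
}

#' @export
print.flatfield_report <- function(x, ...) {
  cat(sprintf("Flat-field report: dI_max = %+.3f %%", x$delta_imax_pct))
  if (!is.na(x$delta_i_pct))
    cat(sprintf(", dI = %.2f %%", x$delta_i_pct))
  cat(sprintf("\n  FWHM CB/SB = %.4f / %.4f  (N = %d / %d)\n",
              x$fwhm_cb, x$fwhm_sb, x$n_cb, x$n_sb))
  invisible(x)
}

#' Detectable-diameter dynamic range
#'
#' Under the sixth-power scattering law, the ratio of the largest to the
#' smallest simultaneously detectable particle diameter on a camera with
#' noise floor I_min and saturation I_max is
#' \eqn{\delta d = (I_{max}/I_{min})^{1/6}}.
#'
#' @param I_min Camera noise floor (counts), > 0.
#' @param I_max Saturation level (counts), > I_min... equality allowed
#'   (ratio 1).
#' @return Diameter ratio (dimensionless, >= 1).
#' @examples
#' dynamic_range(200, 65000) # ~2.6
#' @export
dynamic_range <- function(I_min, I_max) {
  if (any(I_min <= 0) || any(I_max < I_min))
    stop("require 0 < I_min <= I_max", call. = FALSE)
  (I_max / I_min)^(1 / 6)
}
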