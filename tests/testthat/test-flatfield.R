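test_that("bin assignment respects half-open intervals and the channel geometry", {
  sch <- bin_scheme(4)
  expect_equal(as.character(assign_bins(0, sch)), "CB")
  # half-open [lo, hi) intervals: a boundary value belongs to the interval
  # whose lower edge it is
  expect_equal(as.character(assign_bins(2 / 3, sch)), "SB")
  expect_equal(as.character(assign_bins(-2 / 3, sch)), "CB")
  expect_equal(as.character(assign_bins(c(-1.99, 1.2, 5), sch)),
               c("SB", "SB", "none"))
  expect_error(bin_scheme(4, cb = c(-1, 1), sb = list(c(0, 2), c(-2, 0))),
               "overlap")
  expect_error(bin_scheme(4, cb = c(-3, 3)), "within the channel")
})

test_that("bin occupancy of uniform-disc positions matches the chord-area law", {
  sch <- bin_scheme(4)
  p <- bin_occupancy_uniform_disc(sch)
  expect_equal(unname(p["CB"] + p["SB"]), 1, tolerance = 1e-12)
  # brute-force uniform-disc oracle
  set.seed(1)
  n <- 2e5
  r <- 2 * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  lab <- assign_bins(r * cos(th), sch)
  expect_equal(mean(lab == "CB"), unname(p["CB"]), tolerance = 0.01)
  # and the simulated stationary distribution agrees with the same law
  geom <- channel_geometry(2)
  acq <- acquisition_config(n_frames = 30000, seed = 40, substeps = 2)
  traj <- simulate_confined_brownian(2.6, geom, acq)
  frac_cb <- mean(assign_bins(traj$x, sch) == "CB")
  expect_equal(frac_cb, unname(p["CB"]), tolerance = 0.05)
})

test_that("Gaussian histogram fits recover known parameters and reject degenerate data", {
  set.seed(7)
  vals <- rnorm(17632, mean = 1, sd = 0.024)
  fit <- fit_intensity_histogram(vals)
  expect_equal(fit$mu, 1, tolerance = 0.001)
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)) * 0.024, tolerance = 0.05)
  expect_equal(fit$n, 17632)
  # affine equivariance: scaling values scales mu and FWHM
  fit2 <- fit_intensity_histogram(3 * vals)
  expect_equal(fit2$mu, 3 * fit$mu, tolerance = 0.01)
  expect_equal(fit2$fwhm, 3 * fit$fwhm, tolerance = 0.05)
  # occurrence probabilities sum to 1
  expect_equal(sum(fit$histogram$p), 1)
  expect_error(fit_intensity_histogram(rep(1, 200)), "degenerate")
  expect_error(fit_intensity_histogram(rnorm(50)), "at least 100")
})

test_that("peak-difference metric reproduces the reference arithmetic and sign convention", {
  mkfit <- function(mu, sigma = 0.057, n = 1000) {
    structure(list(mu = mu, sigma = sigma, amplitude = 1,
                   fwhm = 2 * sqrt(2 * log(2)) * sigma, n = n,
                   histogram = NULL), class = "gaussian_fit")
  }
  rep1 <- flatfield_metrics(mkfit(1.00001), mkfit(1.00235))
  expect_equal(round(rep1$delta_imax_pct, 2), -0.23)
  expect_equal(flatfield_metrics(mkfit(1.2), mkfit(1.2))$delta_imax_pct, 0)
  # positive when the channel center is brighter
  expect_gt(flatfield_metrics(mkfit(1.1), mkfit(0.9))$delta_imax_pct, 0)
  expect_error(flatfield_metrics(mkfit(-1), mkfit(1)), "positive")
})

test_that("flat-field run is symmetric across bins; guided/leaky profiles are not", {
  geom <- channel_geometry(2, axial_offset = 1000)
  acq <- acquisition_config(n_frames = 30000, seed = 11, substeps = 2)
  traj <- simulate_confined_brownian(ref_D(), geom, acq)
  sch <- bin_scheme(4)
  labels <- assign_bins(traj$x, sch)
  metric_for <- function(field) {
    iv <- scattered_intensity(traj, field, particle_spec(50))
    set.seed(99)
    ni <- normalize_intensity(iv * (1 + rnorm(length(iv), sd = 0.02)))
    flatfield_metrics(fit_intensity_histogram(ni[labels == "CB"]),
                      fit_intensity_histogram(ni[labels == "SB"]), ni)
  }
  flat <- metric_for(illumination_gaussian_beam(ref_beam(), 1000))
  expect_lt(abs(flat$delta_imax_pct), 1)
  expect_equal(flat$fwhm_cb, flat$fwhm_sb, tolerance = 0.1)
  # center-peaked (guided-like) profile with 2.5:1 center/edge contrast
  guided <- metric_for(illumination_radial(function(u) 1 - 0.6 * u^2, 2))
  expect_gt(guided$delta_imax_pct, 10)
  # edge-peaked (leaky-like) profile: sides brighter, sign flips
  leaky <- metric_for(illumination_radial(function(u) 0.4 + 0.6 * u^2, 2))
  expect_lt(leaky$delta_imax_pct, 0)
})

test_that("dynamic range follows the sixth-power law", {
  expect_equal(round(dynamic_range(200, 65000), 1), 2.6)
  expect_equal(dynamic_range(100, 100), 1)
  expect_equal(dynamic_range(10, 640), 2) # 64^(1/6) exactly
  expect_error(dynamic_range(1000, 200), "I_min")
  expect_error(dynamic_range(0, 200), "I_min")
})
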