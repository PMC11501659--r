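test_that("MSD handles stationary and ballistic trajectories in closed form", {
  m0 <- compute_msd(rep(2.5, 100), dt = 1e-3, max_lag = 5)
  expect_true(all(m0$msd == 0))
  expect_equal(m0$n_pairs, 100 - (1:5))
  v <- 3; dt <- 1e-3
  zb <- v * (0:999) * dt
  mb <- compute_msd(zb, dt, max_lag = 4)
  expect_equal(mb$msd, (v * (1:4) * dt)^2, tolerance = 1e-12)
  expect_error(compute_msd(1:10, dt, max_lag = 10), "max_lag")
})

test_that("MSD of simulated free diffusion matches 2 D k dt within Monte-Carlo error", {
  geom <- channel_geometry(1e6) # effectively unconfined
  acq <- acquisition_config(n_frames = 65000, seed = 50, substeps = 2)
  traj <- simulate_confined_brownian(2.6, geom, acq)
  m <- compute_msd(traj$z, dt = 1e-3, max_lag = 4)
  for (k in 1:4) {
    expected <- 2 * 2.6 * k * 1e-3
    # SE of the mean of ~N/k effectively independent squared increments
    se <- expected * sqrt(2 / (m$n_pairs[k] / k))
    expect_lt(abs(m$msd[k] - expected), 3 * se)
  }
})

test_that("MSD estimator is unbiased over replicates", {
  dt <- 1e-3; D <- 2.6; n <- 2000
  set.seed(60)
  msd1 <- replicate(100, {
    z <- cumsum(rnorm(n, sd = sqrt(2 * D * dt)))
    mean(diff(z)^2)
  })
  expected <- 2 * D * dt
  se <- sd(msd1) / sqrt(100)
  expect_lt(abs(mean(msd1) - expected), 2 * se + 1e-12)
})

test_that("first-lags fit recovers D and the intercept exactly on synthetic lines", {
  dt <- 1e-3; D <- 2.23
  m <- compute_msd(rep(0, 100), dt, max_lag = 6)
  m$msd <- 2 * D * m$lag_s # exact line through the origin
  fit <- fit_diffusion(m, n_lags = 2)
  expect_equal(fit$D, D, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  m$msd <- 2 * D * m$lag_s + 0.005 # offset line -> intercept recovered
  fit2 <- fit_diffusion(m, n_lags = 2)
  expect_equal(fit2$D, D, tolerance = 1e-12)
  expect_equal(fit2$intercept, 0.005, tolerance = 1e-12)
  expect_warning(fit_diffusion(m, n_lags = 5), "reduces accuracy")
  m$msd <- -m$lag_s
  expect_error(fit_diffusion(m, n_lags = 2), "negative")
})

test_that("sizing applies the hindrance correction multiplicatively", {
  liq <- ref_liquid()
  expect_equal(size_particle(2.23, liq, hindrance = 1),
               stokes_einstein_d(2.23, liq$viscosity, liq$temperature))
  expect_equal(signif(size_particle(2.23, liq), 3), 58.4)
  d1 <- size_particle(2.23, liq, hindrance = 1)
  d2 <- size_particle(2.23, liq, hindrance = 1.066)
  expect_lt(abs(d2 - d1) / d1, 0.07)
  expect_equal(d2, d1 / 1.066)
})

test_that("block-bootstrap uncertainty is ~0 for deterministic motion and sane for diffusion", {
  dt <- 1e-3
  zb <- 3 * (0:3999) * dt
  u <- d_uncertainty(zb, dt, n_blocks = 10)
  expect_lt(u$se_D / u$D, 1e-9)
  set.seed(61)
  z <- cumsum(rnorm(20000, sd = sqrt(2 * 2.6 * dt)))
  u2 <- d_uncertainty(z, dt, n_blocks = 20, liquid = ref_liquid())
  expect_equal(u2$D, 2.6, tolerance = 0.1)
  expect_gt(u2$se_D, 0)
  expect_lt(u2$se_D / u2$D, 0.05)
  expect_equal(u2$se_d / u2$d_h, u2$se_D / u2$D, tolerance = 1e-9)
  expect_error(d_uncertainty(z[1:50], dt), "too short")
  expect_error(d_uncertainty(z, dt, n_blocks = 2000), "too few")
})

test_that("uncertainty of D scales as 1 / sqrt(N)", {
  dt <- 1e-3; D <- 2.6
  set.seed(62)
  est <- function(n) {
    z <- cumsum(rnorm(n, sd = sqrt(2 * D * dt)))
    fit_diffusion(compute_msd(z, dt, max_lag = 2), 2)$D
  }
  sd_small <- sd(replicate(50, est(2000)))
  sd_large <- sd(replicate(50, est(8000)))
  expect_equal(sd_small / sd_large, 2, tolerance = 0.3)
})
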