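test_that("zero diffusivity freezes the particle; identical seeds reproduce bit-identically", {
  geom <- channel_geometry(2)
  acq <- acquisition_config(n_frames = 50, seed = 5)
  t0 <- simulate_confined_brownian(0, geom, acq, start = c(0.5, -0.3, 2))
  expect_true(all(t0$x == 0.5 & t0$y == -0.3 & t0$z == 2))
  t1 <- simulate_confined_brownian(2.6, geom, acq)
  t2 <- simulate_confined_brownian(2.6, geom, acq)
  expect_identical(t1$z, t2$z)
  expect_identical(attr(t1, "substeps"), attr(t2, "substeps"))
  t3 <- simulate_confined_brownian(2.6, geom,
                                   acquisition_config(n_frames = 50, seed = 6))
  expect_false(identical(t1$z, t3$z))
})

test_that("confinement holds at every substep and axial diffusion is free", {
  geom <- channel_geometry(2)
  acq <- acquisition_config(n_frames = 20000, seed = 8, substeps = 4)
  traj <- simulate_confined_brownian(2.6, geom, acq)
  p <- attr(traj, "substeps")
  expect_true(all(p[, 1]^2 + p[, 2]^2 <= geom$radius^2 + 1e-12))
  # axial (unconfined) per-frame displacement variance = 2 D dt within 3 SE
  dz <- diff(traj$z)
  v <- var(dz)
  expected <- 2 * 2.6 * 1e-3
  se <- expected * sqrt(2 / (length(dz) - 1))
  expect_lt(abs(v - expected), 3 * se)
  # effectively-unconfined variant: transverse variance also free
  wide <- channel_geometry(1e6)
  tw <- simulate_confined_brownian(2.6, wide,
                                   acquisition_config(n_frames = 20000,
                                                      seed = 9, substeps = 4))
  vx <- var(diff(tw$x))
  expect_lt(abs(vx - expected), 3 * se)
})

test_that("stationary transverse distribution is uniform over the channel disc", {
  # pooled thinned samples from replicate runs (transverse mixing time
  # ~ R^2/2D ~ 0.8 s, so 1 s thinning gives near-independent draws)
  geom <- channel_geometry(2)
  r2 <- unlist(lapply(1:6, function(s) {
    acq <- acquisition_config(n_frames = 20000, seed = 100 + s, substeps = 2)
    traj <- simulate_confined_brownian(2.6, geom, acq)
    keep <- seq(1000, 20000, by = 1000)
    (traj$x[keep]^2 + traj$y[keep]^2) / geom$radius^2
  }))
  # for a uniform disc, r^2/R^2 ~ U(0,1)
  counts <- table(cut(r2, breaks = seq(0, 1, by = 0.2)))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("scattered intensity follows the sixth-power law and exposure averaging", {
  geom <- channel_geometry(2)
  acq <- acquisition_config(n_frames = 500, seed = 12)
  traj <- simulate_confined_brownian(2.6, geom, acq)
  uni <- illumination_uniform(3)
  i50 <- scattered_intensity(traj, uni, particle_spec(50))
  expect_true(all(abs(i50 - 3) < 1e-12)) # uniform field -> constant series
  i100 <- scattered_intensity(traj, uni, particle_spec(100))
  expect_equal(i100 / i50, rep(64, 500)) # (2d/d)^6
})

test_that("flat-field illumination yields a quiet intensity series over 65 s", {
  geom <- channel_geometry(2, axial_offset = 1000)
  acq <- acquisition_config(n_frames = 65000, seed = 13, substeps = 2)
  traj <- simulate_confined_brownian(ref_D(), geom, acq)
  field <- illumination_gaussian_beam(ref_beam(), 1000)
  iv <- scattered_intensity(traj, field, particle_spec(50))
  expect_lt(sd(iv) / mean(iv), 0.02)
})

test_that("rendered frames reproduce the Airy pattern and are linear in intensity", {
  geom <- channel_geometry(2)
  acq <- acquisition_config(n_frames = 3, seed = 20)
  still <- simulate_confined_brownian(0, geom, acq)
  cam <- camera_model(photon_scale = 2e4)
  # static bright particle, no noise: diffraction-limited radial profile
  # (fov chosen so the particle sits exactly on a pixel center)
  st <- render_frames(still, rep(1, 3), cam, fov = c(61, 60), noise = FALSE)
  fr <- st$frames[, , 1]
  peak <- which(fr == max(fr), arr.ind = TRUE)[1, ]
  expect_equal(unname(peak), c(31, 31)) # true position rounded to the grid
  prof <- fr[peak[1], peak[2]:60] # radial cut along z
  first_min <- which(diff(prof) > 0)[1] # first upturn = first Airy minimum
  r_min_um <- (first_min - 1) * cam$pixel_pitch
  expect_equal(r_min_um, 0.61 * 0.532 / 0.25, tolerance = 0.15)
  # integrated signal above background linear in input intensity
  sig <- vapply(c(0.2, 0.4, 0.8), function(a) {
    s <- render_frames(still, rep(a, 3), cam, fov = c(61, 60), noise = FALSE)
    sum(s$frames[, , 1] - cam$noise_floor)
  }, 0)
  expect_equal(sig[2] / sig[1], 2, tolerance = 0.01)
  expect_equal(sig[3] / sig[1], 4, tolerance = 0.01)
})

test_that("zero intensity gives pure background at the noise floor; seeds reproduce frames", {
  geom <- channel_geometry(2)
  acq <- acquisition_config(n_frames = 5, seed = 21)
  still <- simulate_confined_brownian(0, geom, acq)
  cam <- camera_model()
  st <- render_frames(still, rep(0, 5), cam, fov = c(30, 80), seed = 3)
  expect_equal(mean(st$frames), cam$noise_floor, tolerance = 0.01)
  expect_true(all(st$frames >= 0 & st$frames <= cam$saturation))
  st2 <- render_frames(still, rep(0, 5), cam, fov = c(30, 80), seed = 3)
  expect_identical(st$frames, st2$frames)
  # undersampled imaging is refused
  expect_error(render_frames(still, rep(0, 5), camera_model(pixel_pitch = 2),
                             fov = c(30, 80)), "undersampled")
})

test_that("trajectory and frame export round-trip through CSV and TIFF", {
  geom <- channel_geometry(2)
  acq <- acquisition_config(n_frames = 5, seed = 22)
  traj <- simulate_confined_brownian(2.6, geom, acq)
  iv <- scattered_intensity(traj, illumination_uniform(), particle_spec(50))
  cf <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, cf, intensities = iv)
  back <- read.csv(cf)
  expect_equal(back$z, traj$z, tolerance = 1e-9)
  expect_equal(back$I_true, iv, tolerance = 1e-9)
  st <- render_frames(traj, iv, camera_model(), fov = c(30, 80))
  tf <- tempfile(fileext = ".tif")
  write_frames_tiff(st, tf)
  pages <- tiff::readTIFF(tf, all = TRUE)
  expect_length(pages, 5)
  expect_equal(round(pages[[1]] * 65535), st$frames[, , 1],
               ignore_attr = TRUE)
})
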