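test_that("blank noise frames yield no detections", {
  geom <- channel_geometry(2)
  still <- simulate_confined_brownian(0, geom,
                                      acquisition_config(n_frames = 20,
                                                         seed = 30))
  cam <- camera_model()
  st <- render_frames(still, rep(0, 20), cam, fov = c(30, 80))
  det <- locate_stack(st)
  expect_equal(nrow(det), 0)
})

test_that("noise-free localization is accurate to a few hundredths of a pixel", {
  geom <- channel_geometry(2)
  acq <- acquisition_config(n_frames = 300, seed = 31)
  traj <- simulate_confined_brownian(ref_D(), geom, acq)
  iv <- scattered_intensity(traj, illumination_gaussian_beam(ref_beam(), 1000),
                            particle_spec(50))
  cam <- camera_model()
  st <- render_frames(traj, iv, cam, fov = c(30, 200), noise = FALSE)
  det <- locate_stack(st)
  expect_equal(nrow(det), 300)
  err_x <- (det$x_um - traj$x_exp) / cam$pixel_pitch
  err_z <- (det$z_um - traj$z_exp) / cam$pixel_pitch
  expect_lt(sqrt(mean(err_x^2)), 0.05)
  expect_lt(sqrt(mean(err_z^2)), 0.05)
})

test_that("default-noise localization RMSE stays under 0.2 px over 1000 frames", {
  geom <- channel_geometry(2)
  acq <- acquisition_config(n_frames = 1000, seed = 32)
  traj <- simulate_confined_brownian(ref_D(), geom, acq)
  iv <- scattered_intensity(traj, illumination_gaussian_beam(ref_beam(), 1000),
                            particle_spec(50))
  cam <- camera_model()
  st <- render_frames(traj, iv, cam, fov = c(30, 200))
  det <- locate_stack(st)
  expect_gte(nrow(det), 999)
  m <- merge(det, data.frame(frame = traj$frame, xt = traj$x_exp,
                             zt = traj$z_exp))
  rmse <- sqrt(mean(((m$x_um - m$xt)^2 + (m$z_um - m$zt)^2) / 2))
  expect_lt(rmse / cam$pixel_pitch, 0.2)
})

test_that("saturated spots are flagged but kept", {
  geom <- channel_geometry(2)
  still <- simulate_confined_brownian(0, geom,
                                      acquisition_config(n_frames = 2,
                                                         seed = 33))
  cam <- camera_model(photon_scale = 2e5) # drives the peak past saturation
  st <- render_frames(still, rep(1, 2), cam, fov = c(30, 80), noise = FALSE)
  expect_equal(max(st$frames), cam$saturation)
  det <- locate_stack(st)
  expect_equal(nrow(det), 2)
  expect_true(all(det$saturated))
})

test_that("greedy linking keeps one track across gaps and respects the search radius", {
  mkdet <- function(frame, z_um, mass = 1000) {
    data.frame(frame = frame, t = frame * 1e-3, x_px = 15, z_px = 0,
               x_um = 0, z_um = z_um, mass = mass, background = 200,
               saturated = FALSE)
  }
  # single detection per frame, small displacements -> one track of length N
  det <- do.call(rbind, lapply(1:20, function(f) mkdet(f, 0.05 * f)))
  tr <- link_trajectories(det, tracking_config(search_radius = 5))
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 20)
  # one missing frame bridged with memory = 1
  det2 <- det[det$frame != 10, ]
  tr2 <- link_trajectories(det2, tracking_config(memory = 1))
  expect_equal(length(unique(tr2$track_id)), 1)
  # but not with memory = 0
  tr3 <- link_trajectories(det2, tracking_config(memory = 0))
  expect_equal(length(unique(tr3$track_id)), 2)
  # a jump beyond the search radius starts a new track
  det4 <- rbind(mkdet(1, 0), mkdet(2, 50))
  tr4 <- link_trajectories(det4, tracking_config(search_radius = 5))
  expect_equal(length(unique(tr4$track_id)), 2)
  # ambiguity: nearer detection wins the existing track
  det5 <- rbind(mkdet(1, 0), mkdet(2, 0.2, mass = 500),
                mkdet(2, 0.9, mass = 5000))
  tr5 <- link_trajectories(det5, tracking_config(search_radius = 5))
  id1 <- tr5$track_id[tr5$frame == 1]
  expect_equal(tr5$track_id[tr5$frame == 2 & tr5$z_um == 0.2], id1)
})

test_that("recovered axial displacements track the truth closely", {
  run <- fixture_run()
  m <- merge(run$track, data.frame(frame = run$traj$frame,
                                   zt = run$traj$z_exp))
  expect_gt(cor(diff(m$z_um), diff(m$zt)), 0.99)
  # and the track covers essentially every frame
  expect_gte(nrow(run$track) / nrow(run$traj), 0.99)
  expect_equal(length(unique(run$track$track_id)), 1)
})

test_that("intensity normalization has unit mean, is idempotent and exact", {
  expect_equal(normalize_intensity(c(1, 2, 3)), c(0.5, 1, 1.5))
  expect_equal(normalize_intensity(rep(7, 10)), rep(1, 10))
  x <- rlnorm(100)
  n1 <- normalize_intensity(x)
  expect_equal(mean(n1), 1)
  expect_equal(normalize_intensity(n1), n1)
  expect_error(normalize_intensity(c(-1, 1)), "zero-mean")
  expect_error(normalize_intensity(1), "at least 2")
})
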