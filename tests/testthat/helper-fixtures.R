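# Shared fixtures: one moderate default-noise synthetic run reused by the
# tracking / flat-field / MSD tests. Built lazily and cached for the session.

ref_beam <- function() gaussian_beam(4.2, 0.532, 1.4607)

ref_liquid <- function() liquid_spec(1.4607, 3.3e-3, 293.15)

# free-solution D of the 50 nm reference particle in the reference liquid
ref_D <- function() stokes_einstein_D(50, 3.3e-3, 293.15)

.fixture_env <- new.env(parent = emptyenv())

# 2,000-frame rendered run at the reference conditions (default noise)
fixture_run <- function() {
  if (is.null(.fixture_env$run)) {
    geom <- channel_geometry(2, axial_offset = 1000)
    acq <- acquisition_config(n_frames = 2000, seed = 42)
    traj <- simulate_confined_brownian(ref_D(), geom, acq)
    field <- illumination_gaussian_beam(ref_beam(), 1000)
    intens <- scattered_intensity(traj, field, particle_spec(50))
    camera <- camera_model()
    stack <- render_frames(traj, intens, camera, fov = c(30, 200))
    det <- locate_stack(stack)
    track <- link_trajectories(det, tracking_config(), camera$pixel_pitch)
    .fixture_env$run <- list(traj = traj, intens = intens, camera = camera,
                             stack = stack, det = det, track = track)
  }
  .fixture_env$run
}
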