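# canta — flat-field capillary-assisted nanoparticle tracking analysis

Nanoparticle tracking analysis (NTA) sizes individual sub-diffraction
particles by tracking their Brownian motion: the diffusion coefficient
estimated from a trajectory's mean squared displacement (MSD) is inverted
through the Stokes–Einstein relation

    D = k_B T / (3 π η d_h)

to a hydrodynamic diameter `d_h`. For fast diffusers, accuracy is limited by
how long a particle stays in the field of view. Capillary-assisted NTA
(CaNTA) confines the particle to a liquid-filled glass microcapillary (bore
~4 µm) illuminated by a wide Gaussian beam; when the liquid's refractive
index matches the cladding (Δn = n_liquid − n_cladding = 0) no modes form in
the channel and the particle sees a *flat field* — spatially invariant
illumination — so ultra-long trajectories (tens of seconds at kHz frame
rates) can be recorded with stable scattered intensity. A mismatch produces
guided (Δn > 0) or leaky (Δn < 0) modes and strong intensity structure.

`canta` is for experiment designers and data analysts in this space. It
implements:

- **Beam optics**: Gaussian-beam design metrics (Rayleigh range, radial
  flatness across the bore, axial decay over a diffusion length), Δn regime
  classification, and a paraxial split-step scalar propagator that
  reproduces the guided/leaky/flat phenomenology of the liquid-filled
  capillary.
- **Transport**: Stokes–Einstein relations (both directions), diffusion
  lengths, Renkin-type hindered-diffusion corrections for a sphere in a
  cylindrical pore, Washburn capillary-filling estimates.
- **Synthetic data**: confined Brownian dynamics (specular reflection at
  the channel wall), sixth-power Rayleigh scattering with exposure-window
  motion blur, and Airy-PSF camera rendering with shot noise, read noise,
  noise floor, quantization and saturation — a full stand-in for the
  experiment with known ground truth.
- **Tracking**: per-frame spot localization (median background, iterated
  circular-mask centroid, sub-0.01 px precision on clean data) and greedy
  nearest-neighbor trajectory linking with gap memory.
- **Flat-field statistics**: central-bin / side-bin (CB/SB) intensity
  histograms, Gaussian fits, the peak-intensity difference
  δI_max = 100·(μ_CB − μ_SB)/μ_CB, the relative intensity spread
  δI = 100·σ_I/Ī, and the detectable-diameter dynamic range
  δd = (I_max/I_min)^(1/6).
- **MSD sizing**: overlapping-pair MSD, first-two-lag linear fit with a
  free intercept (D = slope/2 in 1D), hindrance-corrected sizing, and
  block-bootstrap uncertainties.

## Worked example

Design check and a 10-second synthetic run at the reference conditions
(50 nm gold nanosphere, water/DMSO at η = 3.3 mPa·s and T = 293.15 K in a
4 µm silica bore, 532 nm beam with 4.2 µm waist launched 1 mm away, 1 kHz
frame rate, 0.2 ms exposure):

```r
library(canta)
cfg <- default_config()
str(run_design(cfg), give.attr = FALSE)
#> List of 10
#>  $ rayleigh_range_um   : num 152
#>  $ beam_radius_at_za_um: num 27.9
#>  $ radial_flatness_pct : num 1.02
#>  $ axial_decay_pct     : num 3.5
#>  $ D_dif_um2_s         : num 2.6
#>  $ L_dif_um            : num 18.4
#>  $ delta_n             : num 0
#>  $ regime              : chr "flat"
#>  $ hindrance_factor    : num 1.05
#>  $ dynamic_range       : num 2.62

cfg$acquisition$n_frames <- 10000L
run_full(cfg, seed = 3, verbose = FALSE)
#> CaNTA run (seed 3): 10000 frames, coverage 100.0 %
#>   design : regime flat, flatness 1.02 %, decay 3.50 %
#>   flat   : dI_max +0.332 %, dI 0.86 %
#>   sizing : D = 2.443 +/- 0.045 um2/s, d_h = 50.6 +/- 0.9 nm
```

Reading the output: the beam expands to 27.9 µm at the channel, so the
center-to-edge intensity difference across the 4 µm bore is 1.02 % and the
on-axis decay over one diffusion length (~18 µm) is 3.5 % — a flat field.
The synthetic particle is simulated at the *hindered* diffusivity
D_free/R (R = 1.053 for this geometry), rendered, re-tracked, and the
flat-field metric δI_max stays well under 1 % while the hindrance-corrected
MSD fit recovers the configured 50 nm diameter within its ~1 nm bootstrap
uncertainty. At the full study scale (65,000 frames) the estimate tightens
accordingly (σ_D ∝ 1/√N).

A thin command-line wrapper with per-stage subcommands
(`design|simulate|track|flatfield|msd|full`) ships in `inst/cli/canta.R`:

```sh
Rscript inst/cli/canta.R full --config inst/extdata/example_config.yaml --out out/
```

## Documentation

The methods vignette (`vignettes/canta-methods.Rmd`) describes the model
and its assumptions, the synthetic-data generator and what it does and does
not emulate, numerical choices, and known limitations.
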