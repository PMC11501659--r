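---
title: "Flat-field capillary-assisted NTA: models, simulation and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flat-field capillary-assisted NTA: models, simulation and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canta)
```

## The measurement and its model

Nanoparticle tracking analysis infers a hydrodynamic diameter from the
Brownian trajectory of a single particle. The variant implemented here
confines the particle to a cylindrical microchannel (bore $D_{mc} = 4$ µm by
default) running through a glass capillary, and illuminates the channel with
a freely diffracting Gaussian beam launched by a delivery fiber a distance
$z_a$ before the channel entrance. Two ingredients make the configuration
attractive:

1. **Confinement** keeps a fast diffuser in the field of view indefinitely,
   so trajectories of $N \sim 10^4$–$10^5$ frames are attainable at kHz
   frame rates. Since the standard deviation of the fitted diffusion
   coefficient scales as $\sigma_D \propto 1/\sqrt{N}$, long tracks buy
   statistical accuracy directly.
2. **Flat-field illumination.** If the liquid's refractive index matches
   the capillary glass ($\Delta n = n_{mc} - n_{clad} = 0$), no modes form
   in the channel; the particle then sees the smooth, wide Gaussian beam
   rather than structured modal fields, and its scattered intensity is
   essentially constant as it diffuses. With $\Delta n > 0$ total internal
   reflection creates guided modes (center-concentrated intensity); with
   $\Delta n < 0$ leaky modes drain power transversely (edge-brightened
   intensity). `classify_regime()` encodes exactly this trichotomy, with a
   tolerance band of $5\times10^{-5}$ — an order of magnitude below the
   smallest mismatch of practical interest — treated as matched.

The design calculus is closed-form Gaussian optics. With
$z_R = \pi\omega_0^2 n/\lambda_0$ and
$\omega(z) = \omega_0\sqrt{1 + (z/z_R)^2}$,
$$I(r, z) = \left[\frac{\omega_0}{\omega(z)}\right]^2
  \exp\!\left(-\frac{2r^2}{\omega(z)^2}\right),$$
`radial_flatness()` is $1 - I(D_{mc}/2, z)/I(0, z)$ and `axial_decay()` is
$1 - I(0, z_a{+}\Delta z)/I(0, z_a)$. For the default design (waist 4.2 µm,
532 nm, index ≈ 1.46, $z_a = 1$ mm) the channel sees a ~1 % transverse
variation, and the on-axis intensity drops ~4 % over one diffusion length
$L_{dif} = \sqrt{2D\tau_m} \approx 19$ µm of a 50 nm particle observed for
65 s — small enough that the illumination is operationally flat.

## The scalar propagator

Mismatch phenomenology is demonstrated with a paraxial split-step Fourier
propagator (`propagate()`) on a 2D $(x, z)$ slab: diffraction half-steps in
$k$-space, a phase step $e^{i k_0 (n - n_0)\Delta z}$ for the step-index
profile, and a super-Gaussian absorbing mask so transversely radiated power
leaves the window. This is a deliberate reduction of the full vectorial 3D
problem: it reproduces the *direction* of the guided/leaky/flat behavior
(center/wall intensity ratio above or below 1, and a channel field flat to
better than 2 % when matched) but its magnitudes are not quantitative
predictions for a cylindrical capillary; we treat only the qualitative
structure as meaningful. In homogeneous media the method is exact for
paraxial Gaussians, which the tests exploit: propagated beam radius and
on-axis intensity agree with $\omega(z)$ to well under 1 %, and power is
conserved to ~$10^{-12}$ over a millimeter.

Grid defaults (0.05 µm transverse spacing, 0.25 µm axial step) keep ≥ 10
samples per wavelength in the medium; `propagate()` refuses transverse
spacings above $\lambda_0/2n$ and axial steps above 4 µm rather than
silently aliasing. The regime demonstrations launch a super-Gaussian
flat-top (`field_flattop()`), which avoids the edge diffraction a hard
plane-wave aperture would inject; a Gaussian launch (`field_gaussian()`)
is available for beam-propagation checks.

## What the synthetic generator emulates

`simulate_confined_brownian()` integrates free Brownian motion with
substeps of $\Delta t/\mathrm{substeps}$ (default 10 per 1 ms frame):
each coordinate gains a zero-mean Gaussian increment of standard deviation
$\sqrt{2D\,\delta t}$, and transverse excursions beyond the wall are folded
back by reflecting the radial coordinate ($r \to 2R - r$), the simplest
specular no-flux boundary. The stationary transverse distribution is
uniform over the disc (verified by χ² against the closed-form chord-area
law). Axial motion is unbounded.

Two position sets are recorded per frame: the instantaneous position at
frame start (columns `x, y, z` — unbiased for MSD theory) and the average
over the exposure window (`x_exp, y_exp, z_exp` — what a blur-integrating
camera centroid actually estimates). Motion blur over the 0.2 ms exposure
depresses the measured MSD by a constant $-2D\tau_e/3$, which is precisely
why `fit_diffusion()` fits a *free intercept*: the slope (and hence $D$)
stays unbiased while the intercept absorbs blur and localization error and
serves as a diagnostic (≈ $-4\times10^{-4}$ µm² on clean synthetic data,
matching the closed form).

Scattering uses the Rayleigh sixth-power law: a particle of diameter $d$
scatters $(d/50\,\mathrm{nm})^6$ relative to the 50 nm reference, which is
also what makes the camera dynamic range
$\delta d = (I_{max}/I_{min})^{1/6} \approx 2.6$ for a 16-bit sensor with a
200-count noise floor. `render_frames()` deposits a peak-normalized Airy
pattern (first zero at $0.61\lambda/\mathrm{NA} \approx 1.30$ µm for
NA 0.25) at each exposure substep, then applies Poisson shot noise on the
signal, Gaussian read noise (σ = 5 counts), the 200-count offset, integer
quantization and clipping at 65,000 counts. Depth-of-field defocus is
ignored: the 10× / NA 0.25 objective's ~10 µm depth of field exceeds the
4 µm bore. The axial field of view is a moving window that recenters when
the particle nears an edge, since 65 s of diffusion outruns any fixed
600-pixel window; ground truth keeps absolute coordinates.

Deliberately *not* emulated: plasmonic spectral structure (flat within the
band of interest), thermophoresis and photon pressure (negligible at the
reference power), multi-particle occlusions (the reference experiment
tracks one particle), and temperature-dependent viscosity/index mixing
models (both are config inputs). Passing tests on this generator therefore
demonstrate the correctness of the *analysis chain* under the stated noise
model — not that real videos contain no other systematics (vibration,
drift, aggregates).

Default noise magnitudes are design parameters, not measured values: the
photon scale (880,000 counts per unit scattered intensity) places the 50 nm
reference particle near 20,000 peak counts — mid-range of the 16-bit depth,
so noise floor and saturation both stay relevant — and the pixel pitch
0.345 µm/px corresponds to 3.45 µm sensor pixels behind the 10× objective.

## Tracking

`locate_spots()` re-implements the standard centroid pipeline so the tests
are self-contained: per-frame median background, MAD-scaled threshold
(background + 8·MAD by default), global maxima as seeds, and an *iterated*
circular-mask centroid — re-centering the mask on the running centroid
removes the truncation bias a fixed window has for off-center spots. The
mask diameter (15 px) spans the Airy core and first ring. On noise-free
renders the localization error is ~0.002 px; with the default noise model
~0.005 px, far below the 0.07 µm per-frame diffusion step, which is why
recovered displacement series correlate with truth above 0.999. Saturated
spots are flagged, not dropped. `link_trajectories()` assigns detections to
open tracks greedily by distance (ties to the brighter detection) within a
search radius, bridging up to `memory` missing frames — adequate for the
sparse single-particle regime this targets, and not a multi-hypothesis
tracker.

## Flat-field verification statistics

The channel width is split into a central bin and two side bins (defaults:
thirds of the bore; the exact extents are configurable since reasonable
choices vary). Intervals are half-open $[lo, hi)$ so boundary assignment is
deterministic. Normalized per-frame intensities falling in each bin are
histogrammed (Freedman–Diaconis widths — the binning is not prescribed by
any theory, so a standard adaptive rule is used) and fitted with a Gaussian
by Levenberg–Marquardt least squares, initialized at the sample mean/SD;
constant data and non-convergent fits raise errors rather than returning
garbage. The headline metric
$$\delta I_{max} = 100\,\frac{\mu_{CB} - \mu_{SB}}{\mu_{CB}}\ \%$$
is near zero under flat-field illumination, positive for center-peaked
(guided-like) illumination and negative for edge-peaked (leaky-like)
illumination; the sign convention is fixed by requiring that a
side-bin-brighter configuration yield a negative value. In end-to-end
simulations the flat configuration sits well inside ±1 % while a modest
2.5:1 center/edge guided profile exceeds 10 % — an order-of-magnitude
separation, so the metric discriminates sharply.

## Sizing and uncertainty

`compute_msd()` uses overlapping pairs of *axial* positions only: the
transverse coordinate is confined (4 µm) and would bend a multi-dimensional
MSD downward at accessible lags, while axial diffusion is free. $D$ comes
from the first two lags (configurable, warning above 4 — longer lags have
fewer independent pairs and, under confinement, curvature). Confinement
does still slow axial diffusion through wall hydrodynamics; the Renkin
(Paine–Scherr) centerline polynomial provides the hindrance factor
$R(\lambda) = 1/[(1-\lambda)^2(1 - 2.104\lambda + 2.09\lambda^3 -
0.95\lambda^5)]$, $\lambda = d/D_{mc}$, giving $R = 1.053$ for 50 nm in a
4 µm bore. A more elaborate radially averaged factor was considered and not
adopted: without a specific pore-hydrodynamics reference to pin the radial
weighting, any average would be arbitrary; the centerline value is standard,
documented, and within a percent of plausible averages at this $\lambda$.
The pipeline is self-consistent about it: the generator simulates the
hindered diffusivity $D_{free}/R$ and the sizing step multiplies the
measured $D$ by the same $R$, so recovering the configured free-solution
diameter genuinely exercises the correction.

Uncertainties come from a block bootstrap: the track is cut into 20
non-overlapping segments, $D$ is fitted per segment, and the standard error
of the full-track estimate is $\mathrm{sd}(D_i)/\sqrt{n_{blocks}}$,
propagated to the diameter via $\sigma_d/d = \sigma_D/D$. The $1/\sqrt{N}$
scaling of $\sigma_D$ is verified directly by replicate simulation.

## Configuration and reproducibility

Run configuration is a nested list serialized as YAML (`[optics]`,
`[capillary]`, `[liquid]`, `[particle]`, `[acquisition]`, `[camera]`,
`[tracking]`, `[bins]`, `[msd]` sections; YAML was chosen as the
configuration format because it round-trips R lists natively and is
human-editable). All stochastic stages draw exclusively from R's RNG —
including the compiled rendering and walk kernels — so a single seed makes
trajectories, frames and reports bit-reproducible; `run_full()` derives
per-chunk rendering seeds deterministically from the run seed. Every stage
persists its intermediates (CSV/TIFF/JSON) and can be re-run in isolation
via the CLI wrapper.

## Problem sizes used in the test suite

Unit tests run the generator at $10^3$–$3\times10^4$ frames, which is where
the Monte-Carlo error bars of the assertions (3 standard errors for MSD
checks, χ² at α = 0.01 for the disc-uniformity test on ~1 s-thinned,
near-independent samples) are meaningful without being wasteful; the
end-to-end recovery check runs the full 65,000-frame acquisition with a
30 × 200 px rendering window, processed in 5,000-frame chunks so the image
stack never resides in memory at once. The scaling test for $\sigma_D$ uses
50 replicates at 4,000 and 16,000 frames with a ±30 % band on the expected
factor-2 ratio.

## Known limitations

- The propagator is scalar, paraxial and 2D; guided/leaky magnitudes
  (e.g. center/wall ratios) are qualitative.
- The hindrance model is a centerline approximation; at $\lambda > 0.2$ it
  should not be trusted, and the implementation refuses $\lambda \ge 1$
  only as a hard error.
- The tracker is single-particle by design: dense scenes, occlusions and
  heterogeneous PSFs are out of scope.
- Experimental values that depend on unavailable raw video (measured
  intensity spreads, bin counts, fitted FWHMs) are used only as
  plausibility references, never asserted by the tests.
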