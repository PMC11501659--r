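Package: canta
Title: Flat-Field Capillary-Assisted Nanoparticle Tracking Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Design, simulation and analysis tools for flat-field
    capillary-assisted nanoparticle tracking analysis (CaNTA), in which a
    nanoparticle diffusing inside a liquid-filled glass microcapillary is
    illuminated by a wide Gaussian beam and tracked through its laterally
    scattered light. Provides analytic Gaussian-beam design metrics and a
    paraxial split-step scalar beam propagator for refractive-index-mismatch
    regimes (guided, leaky, flat); Stokes-Einstein relations, diffusion
    lengths, hindered-diffusion corrections and capillary filling times; a
    synthetic optofluidic video generator (confined Brownian dynamics,
    sixth-power Rayleigh scattering, Airy-pattern camera rendering with shot
    and read noise); single-particle localization and trajectory linking;
    flat-field verification statistics (central/side-bin intensity
    histograms, Gaussian fits, peak-difference and dynamic-range metrics);
    and mean-squared-displacement estimation of diffusion coefficients and
    hydrodynamic diameters with block-bootstrap uncertainties.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
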