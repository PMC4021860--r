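Package: sptkit
Title: Single-Particle Tracking Simulation and Diffusion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-molecule tracking (SMT) studies of membrane
    diffusion. Monte-Carlo simulation of two-dimensional Brownian motion in
    simple, state-switching, and domain-obstructed modes with optional
    localization noise; import and exclusion-criteria filtering of particle
    tracking trajectories (ImageJ Mosaic Particle Tracker reports or generic
    delimited tables); mean square displacement (MSD) curves with Brownian,
    anomalous, flow, and confined model fits, static and dynamic localization
    errors and optimal time-lag selection; multi-population decomposition via
    cumulative probability distribution (CPD) fits of squared displacements
    with F-test order selection; and Arrhenius analysis of
    temperature-dependent diffusion coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
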