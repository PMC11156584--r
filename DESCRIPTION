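Package: brainclear
Title: Biophysical Models of Brain Solute Diffusion and Clearance
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Forward models and fitting tools for measuring solute transport
    in brain tissue with fiber photometry. Implements the Gaussian
    volume-source diffusion model and its photobleaching-recovery (FRAP)
    form, bulk-flow advected variants, slab-efflux diffusimetry, and
    saturating clearance kinetics; estimates diffusion coefficients and
    clearance half-times from fluorescence traces with cubic-spline
    baseline correction; fits Gaussian histology profiles and linear
    intensity calibrations; scores vigilance states (Wake/NREM/REM) from
    EEG/EMG band-power and EMG-tone features with a Gaussian mixture
    model; and provides bias-corrected and accelerated (BCa) bootstrap
    estimation statistics. Seeded synthetic-data generators emulate the
    photometry, histology and sleep-feature recordings the analysis
    expects, so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    minpack.lm,
    purrr,
    rlang,
    signal,
    splines,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
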