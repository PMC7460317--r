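Package: mangroveCr
Title: Coupled Tidal Hydrodynamics, Chromium Transport and Mangrove Uptake
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for chromium fate in tidal mangrove estuaries. Couples
    a depth-averaged shallow-water solver on a staggered Cartesian grid with
    finite-volume advection-dispersion transport of dissolved chromium and a
    per-cell linear compartment model for chromium in the soil liquid, soil
    solid and plant pools. Includes harmonic tidal boundaries with wetting
    and drying, industrial point sources gated by a daily discharge window,
    constructed-wetland pretreatment units, a scenario engine (baseline,
    deforestation, constructed wetlands, no-ecosystem) with exact mass-budget
    accounting, Nash-Sutcliffe / index-of-agreement / RMSE model-efficiency
    metrics, kinetic parameter estimation from greenhouse time series, and
    deterministic synthetic fixtures (idealized tidal channels, a toy
    two-bank catchment, greenhouse datasets).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
LinkingTo:
    Rcpp
Config/testthat/edition: 3
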