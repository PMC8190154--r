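Package: fieldET
Title: Daily Field-Scale Crop Water Use from NDVI Phenology and Tower
    Meteorology
Version: 0.1.0
Authors@R:
    person("Mara", "Jensen", email = "mara.jensen@example.org",
           role = c("aut", "cre"))
Description: A pipeline for mapping daily crop water use at metre scale by
    forcing the Priestley-Taylor PT-JPL evaporation model with daily NDVI
    rasters and hourly eddy-covariance tower meteorology. Includes
    quality control and energy-balance-closure correction of AmeriFlux-style
    tower records, the three-component (soil, canopy, interception) latent
    heat flux model driven by NDVI-derived biophysical constraints, water
    depth accounting (daily aggregation, Savitzky-Golay smoothing, cumulative
    budgets, zonal statistics, underperformance mapping), evaluation
    statistics against closure-corrected tower fluxes, and a fully seeded
    synthetic scene generator (double-logistic phenology with heterogeneity
    patches, diurnal meteorology with stochastic cloud attenuation, tower
    records with an imposed closure gap) so the whole analysis is testable
    without proprietary imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
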