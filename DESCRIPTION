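Package: tidalmarsh
Title: Early Indicators of Tidal-Flat to Salt-Marsh Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects early indicators of the ecosystem-state transition from
    bare tidal flat to vegetated salt marsh. Provides tidal-exposure metrics
    (the frequency of skipped tidal inundations) from tide-gauge records,
    micro-topography intensity mapping from near-infrared orthophotos,
    NDVI-based vegetation classification with per-scene bimodal thresholds,
    hypsometric and trend analyses, binned vegetation-establishment
    probability surfaces, and a nonlinear-diffusion simulator of thin-layer
    surface-water drainage over an inclined plane that explains why
    micro-topographic patterns form only on gently sloping flats. A fully
    synthetic estuary generator with known ground truth makes every stage
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    broom,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
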