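Package: hexrich
Title: Hexagon-Binned Species Richness and Upwelling Overlap from Animal Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for macroecological analysis of multi-species animal
    tracking data: equal-area tessellated hexagon grids for binning
    location fixes, relative species-richness surfaces, overlap statistics
    with named ocean regions such as the Canary Current upwelling,
    accessibility-based null-usage surfaces, and penalized additive
    modelling of richness against sea-surface temperature, chlorophyll,
    spatial position and null usage, with variance-inflation screening,
    all-subsets AIC selection, residual variograms and smooth-peak
    inference. Includes a seeded synthetic-study generator (tracks,
    environmental fields, region polygon, truth record) so the full
    pipeline is testable end to end without satellite or archival-tag
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    mgcv,
    ncdf4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
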