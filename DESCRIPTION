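Package: docseer
Title: Seasonal Forecasting of Riverine Dissolved Organic Carbon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for seasonal forecasting of riverine
    dissolved organic carbon (DOC) in Mediterranean drinking-water catchments:
    synthetic climate ensembles with controllable skill and bias, empirical
    quantile mapping bias correction with leave-one-year-out cross-validation,
    a minimal semi-distributed rainfall-runoff and soil-carbon/DOC simulator
    with warm-up and state resets, CRPS/CRPSS probabilistic verification over
    initialization months and lead times, and tercile forecast products mapped
    to management action levels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
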