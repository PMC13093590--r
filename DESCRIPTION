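Package: roadhot
Title: Road Encounter Hotspots and Landscape Connectivity from Sparse
    Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts wildlife road-encounter hotspots from sparse,
    opportunistically collected occurrence records. Provides matched
    pseudoabsence (null point) sampling along linearly referenced road
    networks, per-point landscape covariates (wetland distances,
    multi-scale land-cover buffer composition), exhaustive AIC-ranked
    logistic model selection, network-constrained kernel density
    estimation with Monte-Carlo significance envelopes for hotspot
    detection, least-cost-path connectivity over a resistance surface,
    and validation of detected hotspots against predicted movement
    corridors. A synthetic landscape generator emulates the statistical
    structure of rural wetland-rich study regions so the full pipeline is
    reproducible without sensitive species location data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
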