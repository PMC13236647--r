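Package: greenmood
Title: Seasonal Spatial Analysis of Urban Green Space and Negative Emotions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how multidimensional urban green space
    characteristics relate to community-level negative emotions across
    seasons. Builds population-standardized negative-emotion indicators
    from geotagged, sentiment-labeled posts via kernel density estimation;
    computes green-space quantity, quality, and landscape-pattern
    covariates (NDVI, street-view greenery, walking-catchment
    accessibility, LPI/PD/ED/SHDI); quantifies spatial clustering with
    global and local Moran's I; fits and compares global random forests,
    geographically weighted regression, and geographically weighted random
    forests with adaptive neighborhoods; and interprets fitted models with
    Shapley attribution, seasonal partial-dependence curves, and
    per-community dominant-factor maps. A synthetic-city generator with
    known ground truth makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
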