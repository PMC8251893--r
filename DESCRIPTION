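Package: mangroveflux
Title: Projected Carbon Dioxide Emissions from Global Mangrove Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort-based projection of future CO2-equivalent emissions from
    mangrove deforestation at the marine-province scale. Implements an
    exponential area-decay model with per-cohort exponential carbon release,
    counterfactual foregone soil-carbon sequestration, driver-weighted
    emission factors for five proximate drivers of loss (commodities,
    erosion, clearing, extreme climatic events, settlement), global hotspot
    ranking, a scenario/sensitivity grid with parameter derivatives and
    elasticities, and a seeded synthetic province-table generator for fully
    reproducible desk-scale runs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
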