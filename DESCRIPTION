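Package: thermofill
Title: Thermal Niche Filling of Ectotherm Ranges from Tolerance Limits and Gridded Climate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spatially explicit pipeline for quantifying how well ectotherm
    species fill their potential thermal niches. Converts species thermal
    tolerance limits (CTmax/CTmin) and gridded climatologies into per-species
    extreme body temperatures (a lumped-parameter operative-temperature model
    in sun and shade on land, sea-surface extremes in the ocean, the more
    extreme medium in intertidal coastal cells, with seasonal dormancy
    masking), constructs potential thermal ranges by realm, thermal and
    depth/elevation restriction, and computes warm/cool niche filling, range
    filling and the equatorward bias of range underfilling. Includes
    acclimatization and behavioural-thermoregulation sensitivity analyses,
    latitudinal trend models, and synthetic world and species generators
    with explicit hypothesis scenarios for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    stats,
    utils,
    withr,
    geosphere,
    car,
    generics
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest
Config/testthat/edition: 3
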