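Package: wardmix
Title: Hospital Colocation Contact Networks and Patient Mixing Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds daily colocation contact networks from hospital
    admission-discharge-transfer (ADT) encounter records, computes
    network-level measures (density, degree, betweenness, closeness,
    modularity, diameter) and their association with hospital size, and
    derives length-of-stay-weighted mixing matrices stratified by patient
    age, Elixhauser comorbidity score, and antibiotic spectrum rank.
    Includes a synthetic multi-hospital encounter-data generator with
    configurable unit archetypes, significance testing for distributional
    comparisons, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
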