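Package: asrwi
Title: Welfare Assessment and Inter-Observer Reliability for Small
    Ruminants in Hot-Arid Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Arid-Hot Small Ruminant Welfare Index (ASR-WI),
    a multi-assessor welfare scoring protocol for intensively kept sheep and
    goats in hot-arid climates. Provides a packaged registry of 24 welfare
    indicators across four domains (behaviour and mental state, environment,
    nutrition, health), validation and ingestion of long-format multi-assessor
    scoring sheets, generalized Fleiss' kappa with percentage agreement and
    Landis-Koch interpretation bands, reliability-gated indicator selection
    (kappa >= 0.35), normalized 0-100 domain scores and the weighted composite
    index, and a seeded synthetic multi-rater panel generator with closed-form
    agreement oracles for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
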