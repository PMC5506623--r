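Package: mnchimpact
Title: Forecasting Lives Saved and Costs of Maternal, Newborn, and Child
    Health Innovations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A country-year forecast engine for estimating the incremental
    lives saved and incremental costs of introducing maternal, newborn, and
    child health innovations into a home/clinic/hospital care cascade.
    Expected deaths per condition are computed from target population,
    incidence, setting mix, intervention coverage and effectiveness, and
    case fatality rates for treated and untreated cases; an innovation
    perturbs the cascade through one of six mechanism classes (incidence
    reduction, mortality reduction, coverage expansion, second-line
    treatment, adherence boost, diagnostic improvement) with a linear
    adoption ramp. Ships eight innovation presets, one-at-a-time
    sensitivity analysis, an incremental costing module, a seeded
    synthetic-data generator, and a per-individual microsimulation oracle
    for validating the deterministic engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
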