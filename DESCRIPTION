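Package: pmscost
Title: Activity-Based Costing of Medicine Quality Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the financial and economic cost of post-market
    medicine sampling and quality testing programmes using activity-based
    microcosting. Ingests delimited cost ledgers and fieldwork logs,
    converts currencies, annualises capital with the equivalent annual
    cost method, applies overhead rules, and aggregates costs by
    component and study phase. Propagates day-to-day uncertainty in
    sample collection into unit costs (per sample collected, per
    substandard sample detected, per fieldwork day and week) with a
    stratified bootstrap and percentile confidence intervals, runs
    one-way sensitivity scenarios, computes workload indicators from
    time-and-motion records, and generates synthetic inputs with the
    statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
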