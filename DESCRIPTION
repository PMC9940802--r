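Package: cvmcost
Title: Time-Driven Activity-Based Costing for Continuous Virtual
    Monitoring Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A config-driven costing engine for hospital continuous
    virtual monitoring (CVM) programs, built on time-driven
    activity-based costing (TDABC). Reads daily call ledgers, prices
    averted in-person interactions (staff donning/doffing time and
    personal protective equipment changes) against program equipment
    cost, and reports the savings decomposition with return on
    investment. Includes staffing-scenario adjustment, one-way
    parameter sweeps, breakeven analysis, and a seeded synthetic
    ledger generator. All currency arithmetic is exact in integer
    cents with round-half-up display conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
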