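Package: hemecon
Title: Economic Burden of Hematologic Malignancies via VSLY Valuation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monetizes disability-adjusted life years (DALYs) lost to
    hematologic malignancies using benefit-transferred value-of-statistical-
    life-year (VSLY) estimates, and analyses the resulting economic burden:
    aggregation by country, income group and disease subtype; exact Shapley
    decomposition of cost change into VSLY, population growth, population
    aging and epidemiological components; deterministic scenario and Bayesian
    age-period-cohort (RW2-prior) projection to 2050; and percentile bootstrap
    uncertainty intervals. Ships a synthetic-data generator that emulates
    GBD-results-style DALY tables, World Bank economic indicators and UN-style
    demography so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
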