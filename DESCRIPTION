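Package: strikesim
Title: Lightning-Induced Tree Mortality in Cohort-Structured Forest Stands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate empirical lightning mortality rates from
    strike-survey tables, simulate stochastic lightning-induced tree kills on
    cohort-structured forest patches with an extended flashover target area,
    attribute tree and biomass mortality by cause in multi-century stand
    simulations, and build gridded cloud-to-ground lightning density
    climatologies from labelled flash records. Includes synthetic-data
    generators so the whole pipeline is testable without field downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
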