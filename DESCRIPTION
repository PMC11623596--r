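Package: litdark
Title: Thermodynamics of Light-Switchable Enzyme Allostery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for optogenetic enzyme photoswitches measured
    under lit and dark conditions. Extracts catalytic turnover from
    absorbance progress curves, fits transition-state thermodynamics
    (activation enthalpy and entropy) by Eyring analysis with bootstrap
    errors, quantifies lit-minus-dark allosteric energetics and their
    temperature dependence, fits two-state thermal denaturation models to
    circular dichroism melts with light-pulse artifact removal and
    aggregation-aware fit windows, and aggregates per-variant results into
    enthalpy-entropy tradeoff and stability-activity analyses. Includes a
    seeded synthetic-data generator that emulates the raw measurements so
    the full pipeline is testable end to end.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
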