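Package: pharmera
Title: Tiered Environmental Risk Assessment for Pharmaceuticals in Surface Waters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A substance-agnostic pipeline for tiered environmental risk
    assessment (ERA) of active pharmaceutical ingredients in surface waters.
    Derives initial and refined predicted environmental concentrations (PECs)
    from sales data, fits first-order biodegradation kinetics and an
    approximate sewage-treatment removal estimator, derives predicted no-effect
    concentrations (PNECs) from chronic ecotoxicity endpoints and from bacterial
    minimum inhibitory concentration (MIC) distributions (antibiotic-resistance
    PNECs), summarises censored (nondetect-containing) measured concentration
    datasets by substitution and percent ranking, characterises risk through
    quotients and exceedance fractions, assesses secondary poisoning of top
    predators and humans through acceptable-daily-exposure factor chains, runs
    a persistence/bioaccumulation/toxicity screen, and simulates concentration
    fields over tree-shaped river networks. Ships the published constants for
    mycophenolic acid and its prodrug mycophenolate mofetil as a worked fixture,
    plus seeded synthetic-data generators for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
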