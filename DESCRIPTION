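Package: cirvi
Title: Pharmacovigilance Analysis of Complement-Inhibitor Viral Infection
    Adverse Events in FAERS-Format Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for spontaneous-report safety analysis
    of complement inhibitors (C3, C5 and Factor B classes) used in
    paroxysmal nocturnal hemoglobinuria. Reads FAERS-format quarterly ASCII
    tables, applies a two-stage deduplication and exclusion protocol,
    computes eight disproportionality signal-detection statistics (ROR,
    PRR, chi-square, Fisher exact, observed-to-expected, two BCPNN
    variants, and EBGM via the multi-item gamma-Poisson shrinker) with a
    composite criterion for complement-inhibitor-related viral infection
    adverse events, performs time-to-onset analysis, and fits fatality
    risk models (logistic regression, restricted cubic splines with
    AIC-selected knots, stratified odds ratios with Haldane-Anscombe
    correction). Ships a synthetic FAERS-report generator with planted
    effect sizes so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
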