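Package: starvalue
Title: Standardised-Rate Variation and STAR Value-for-Money Analysis for
    Back-Pain Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population value-improvement analysis of elective
    back-pain care. Simulates patient-level hospital episode data with
    practice- and deprivation-structured variation; computes crude and
    European Standard Population age-sex directly standardised rates per
    10,000 with 95% confidence intervals (Wilson score for crude
    proportions, Dobson-style gamma intervals for standardised rates);
    quantifies between-practice fold-variation and its relationship to
    practice deprivation; analyses procedure rates and age at first
    procedure by deprivation decile; and implements the Socio-Technical
    Allocation of Resources (STAR) value-for-money computation:
    per-intervention value triangles, slope-ordered efficiency frontiers,
    portfolio summaries, and budget-neutral disinvestment/reinvestment
    plans evaluated in QALYs.
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
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
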