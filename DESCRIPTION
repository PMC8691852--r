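Package: ppmsbound
Title: Privacy-Preserving Periodical Publication of Spontaneous Reporting
    System Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Anonymizes periodically published spontaneous-reporting-system
    (adverse drug event) tables so that equivalence groups remain safe against
    backward, forward, latest, medication-discontinuation and
    substantial-symptoms attacks.  Implements the PPMS(k, theta, alpha)-bounding
    model and its greedy heuristic grouping algorithm, adversary auditors for
    the five attacks, the DIR/DSR/SSGR security ratios, a normalized
    information-loss utility metric, and a seeded generator of multi-quarter
    synthetic cohorts with case follow-up.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
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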