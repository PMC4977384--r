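Package: chfmarkov
Title: Markov Cohort Modelling of Home Telehealth for Congestive Heart Failure
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A monthly-cycle Markov cohort model of congestive heart failure
    (CHF) progression, where living states count prior hospital admissions,
    together with an economic layer for a home telehealth monitoring and
    early-treatment program. Computes incremental cost, life years and
    hospital admissions of telehealth versus usual care; supports one-way and
    two-way deterministic sensitivity analyses, break-even monthly fee
    solving, lifetime-cost and national-burden validation runs, and an
    individual-level Monte Carlo microsimulation that serves as a stochastic
    oracle for the deterministic engine. All results are returned as tibbles
    and plotted with ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
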