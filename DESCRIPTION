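Package: pdcsurv
Title: Adjusted Proportion of Days Covered and Time-Dependent Survival
    Models for Pharmacy Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring medication adherence from administrative
    pharmacy-claims data and for relating adherence to mortality.
    Implements an adjusted proportion-of-days-covered (PDC) engine with
    completion-date supply chaining, early-refill deferral, end-of-follow-up
    truncation and hospital-day removal; builds both a fixed summary
    adherence measure and repeated 102-day interval measures with supply
    carryover; constructs fixed and counting-process survival datasets and
    fits Cox proportional-hazards models for both measurement approaches,
    with Kaplan-Meier description, concordance-over-time, proportional
    hazards diagnostics, collinearity screening and a sensitivity suite.
    Includes a synthetic claims generator with configurable dependence
    among latent health, refill behaviour and mortality, including a
    survival-bias scenario in which the two measurement approaches diverge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
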