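Package: onearmtte
Title: Single-Arm Time-to-Event Trials with Joint Non-Inferiority and
    Superiority Objectives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design, analysis and simulation of single-arm phase II
    survival trials that pre-specify both a non-inferiority and a
    superiority hypothesis against a historical control. Derives the
    non-inferiority margin by the fixed-margin method from a historical
    active-versus-placebo hazard ratio; sizes the trial with the
    exponential maximum-likelihood events formula under uniform accrual,
    minimum follow-up and dropout inflation; tests the two hypotheses
    hierarchically (non-inferiority first, then superiority at the same
    unadjusted one-sided level); supports a nonparametric Kaplan-Meier
    median confidence-interval decision rule; and verifies operating
    characteristics by Monte Carlo simulation of patient-level trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
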