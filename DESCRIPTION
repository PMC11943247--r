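Package: faersignal
Title: Pharmacovigilance Signal Detection on FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance pipeline for spontaneous
    adverse-event reporting data in the FDA Adverse Event Reporting System
    (FAERS) quarterly ASCII dialect: ingestion and FDA-recommended case
    deduplication, quarterly deletion-list handling, preferred-term to
    system-organ-class coding via a user-supplied dictionary table,
    primary-suspect cohort selection with descriptive summaries, and
    disproportionality analysis with four signal-detection statistics
    (reporting odds ratio, proportional reporting ratio with the MHRA
    combined criterion, the Bayesian confidence propagation neural network
    information component, and the multi-item gamma Poisson shrinker with
    an empirical-Bayes two-component gamma prior). Time-to-onset is
    modelled with a Weibull distribution and classified by hazard profile.
    A synthetic FAERS generator with planted drug-event signals provides
    ground truth for validating every stage without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
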