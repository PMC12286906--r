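Package: depcem
Title: Markov Cohort Cost-Effectiveness Model of Dependence in Dementia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-state Markov cohort model (low, moderate, and high
    dependence, and dead) for evaluating the cost-effectiveness of
    hypothetical independence-preserving interventions in people with
    dementia, from the perspective of the health and social care provider
    in England. Includes the parameter-derivation stages (BADLS severity
    categorisation, interval-censored transition-probability estimation
    from longitudinal panel data, survival-to-cycle death-probability
    conversion, and state-utility estimation), incremental
    cost-effectiveness analysis with dominance classification and
    threshold-effect search, a deterministic sensitivity-analysis scenario
    suite, convention calibration against published base-case anchors, and
    synthetic-data generators for trial-like end-state cohorts and
    longitudinal BADLS panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
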