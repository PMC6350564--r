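Package: opepcua
Title: Markov Cohort Cost-Utility Analysis of Oscillating PEP Therapy in COPD
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A four-state, twelve-cycle Markov cohort model comparing an
    oscillating positive expiratory pressure (OPEP) airway-clearance device
    against usual care without PEP therapy in patients recovering from a
    COPD exacerbation. Implements the full cost-utility workflow: parameter
    validation and derivation of composite inputs (severity-weighted
    utility, outpatient follow-up cost, monthly utility decrements),
    cohort simulation with explicit accounting conventions, incremental
    cost-effectiveness and dominance classification, one-way deterministic
    sensitivity analysis with tornado ordering, probabilistic sensitivity
    analysis with method-of-moments beta/gamma/log-normal distributions,
    cost-effectiveness plane summaries and acceptability curves, and a
    patient-level microsimulation used as an independent validation oracle.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
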