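Package: obstrigger
Title: Obstetric Adverse Drug Event Trigger Tool
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated screening of structured obstetric inpatient records for
    adverse drug events (ADEs) using a declarative trigger rule engine. Ships a
    39-item obstetric trigger registry organised into laboratory, medication,
    symptom and outcome modules, the IHI Global Trigger Tool medication-module
    comparator, and a revised 35-item registry. Trigger hits are adjudicated
    with a WHO-UMC causality cascade and CTCAE v5 severity grading, and the
    package computes the full surveillance metric surface: per-trigger positive
    predictive values, ADE incidence per 100 admissions and per 1000
    patient-days, and three-way method comparison against spontaneous
    reporting. Includes a synthetic cohort generator with known ground truth
    and a deterministic study fixture for end-to-end validation, plus a
    trigger refinement procedure that drops silent rules and tightens
    low-precision ones.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    tibble,
    dplyr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
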