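Package: pdcgrowth
Title: Growth Monitoring Decision Support and Audit for High-Risk Infant Clinics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the clinical algorithm of a paediatric development
    clinic (PDC) growth-monitoring tool for preterm and low-birthweight
    infants -- corrected gestational age, LMS-based anthropometric z-scores
    with the WHO restricted adjustment, interval weight gain, and a
    rule-based nutritional classification with colour coding -- together
    with the evaluation machinery used to audit such a tool against
    electronic medical records: visit-level completeness and concordance
    tallies by exposure group, child-level nutritional status at target
    corrected ages, and difference-in-difference estimation with
    facility-clustered robust standard errors. A seeded synthetic EMR
    generator reproduces the cohort structure (visit schedules, preterm
    case mix, nurse recording behaviour) so the full pipeline runs without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
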