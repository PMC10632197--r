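Package: bdscreen
Title: Automated Screening for Impending Brain Death in Neurocritical Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule engine, evaluation statistics and cohort simulator for
    automated 12-hourly screening of neurocritical-care patients at risk of
    brain death. The screening rule flags coma (Richmond Agitation Sedation
    Scale -4/-5 or Glasgow Coma Scale 3-6) combined with bilaterally absent
    pupillary light reflexes from routinely charted observations, emits a
    notification log with ancillary clinical flags (ventilation, intracranial
    pressure, cerebral perfusion pressure, serum sodium, resuscitation), and
    evaluates patient-level diagnostic accuracy against a brain-death
    reference standard: sensitivity, specificity, predictive values and
    overall accuracy with exact (Clopper-Pearson), Wilson score and
    logit-scale predictive-value confidence intervals, subgroup analyses and
    2x2 odds ratios. A synthetic neurocritical-care cohort generator makes
    the whole pipeline testable end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
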