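Package: iodstatus
Title: Population Iodine Status from Spot and 24-Hour Urine Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing population iodine status from urinary
    biomarkers. Predicts 24-hour urinary creatinine excretion from
    anthropometry (Tanaka, Kawasaki and Mage equations), extrapolates spot
    urinary iodine concentrations to predicted 24-hour iodine excretion,
    converts excretion to estimated intake, classifies individuals against
    the Estimated Average Requirement (EAR cut-point method) and populations
    against median urinary iodine concentration cut-offs, and quantifies
    agreement between predicted and measured 24-hour excretion with Cohen's
    kappa, sensitivity/specificity and ratio-scale (log-transformed)
    Bland-Altman limits of agreement. Includes a synthetic cohort generator
    with known ground truth for validating every pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    knitr,
    rmarkdown
Config/testthat/edition: 3
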