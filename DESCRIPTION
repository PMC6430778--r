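Package: dentalage
Title: Dental Age Estimation and Population-Specific Calibration with
    Demirjian's Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for radiographic dental age estimation in children using
    Demirjian's seven-tooth method: developmental staging with contralateral
    substitution, sex-specific self-weighted maturity scores, conversion of
    maturity scores to estimated dental ages, age-group-stratified accuracy
    assessment against chronological age, calibration of a population-specific
    logistic growth prediction model CA = 1/(a + b*c^DMS), intra- and
    inter-rater reliability statistics (percent agreement, Cohen's kappa,
    test-retest correlation), finite-population sample-size calculation, and a
    seeded synthetic-cohort generator so every pipeline stage is testable
    without radiographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
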