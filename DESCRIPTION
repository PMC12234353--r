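Package: exposomekit
Title: Chemical Exposomics of Biobanked Plasma: Quantification, Feature
    Processing, Annotation and Risk-Factor Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for LC-HRMS chemical exposomics of longitudinal biobank
    plasma cohorts. Implements targeted quantification from internal-standard
    calibration curves with left-censoring substitution (MLOQ/2, MLOQ/4) and
    isomer summation; untargeted feature-table treatment (procedural-blank
    ratio filtering, ESI+/- neutral-mass merging, internal-standard PCA
    normalization, blank subtraction with area floor, correlation-based
    deduplication, detection-frequency filtering); confidence-levelled
    spectral-library annotation with environmental/endogenous classification;
    and subject-random-intercept linear mixed models relating chemical levels
    to reproductive breast-cancer risk factors with tiered multiplicity
    control. A synthetic-cohort generator emulates the longitudinal study
    design (parity strata, repeated sampling visits, injection batches) so the
    whole pipeline is testable without restricted individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    lmerTest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
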