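Package: lungwater
Title: Quantitative-CT Extravascular Lung Water and ECBF-Corrected
    Thermodilution Estimates
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes the extravascular lung water index from chest CT
    volumes in Hounsfield units and aligned binary lung masks (HU-window
    densitometry, height-predicted expected lung weight, normalisation to
    ideal body weight), derives an extracorporeal-blood-flow (ECBF)
    correction factor for transpulmonary-thermodilution EVLWI by multiple
    linear regression, and provides the method-agreement and study-design
    statistics used to validate such corrections (Bland-Altman bias and
    limits of agreement with precision-based sample sizing, paired power,
    normality-gated paired comparison, Spearman correlation, DICE overlap).
    Includes generators for ground-truth-known CT phantoms and synthetic
    patient cohorts so the whole pipeline is testable without clinical data,
    a minimal NIfTI-1 reader/writer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
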