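Package: purkinjetrials
Title: In Silico Drug Trials on Populations of Cardiac Purkinje Cell Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates drug-induced electrophysiological changes in human
    cardiac Purkinje cells and classifies proarrhythmic (torsade de pointes)
    risk. Provides a reduced twelve-current Purkinje action-potential model,
    construction and biomarker-based calibration of populations of models via
    Latin hypercube sampling of ionic conductances, IC50 pore-block drug
    application, multi-rate pacing trials with early-afterdepolarization
    detection, risk classification against CredibleMeds torsade classes, and a
    synthetic rabbit Purkinje fiber assay generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
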