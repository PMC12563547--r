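Package: asymali
Title: Analysis Pipeline for Transpulmonary-Pressure-Guided Ventilation in
    Asymmetric Acute Lung Injury
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing porcine models of asymmetric acute lung
    injury ventilated with transpulmonary-pressure (TPP)-guided versus fixed
    PEEP. Computes derived respiratory mechanics (driving pressure,
    transpulmonary pressures, mechanical power, quasi-static compliance) from
    hold-maneuver readings, simulates the hourly TPP-targeted PEEP titration
    rule, scores histology fields with a modified lung injury score and CT
    regions with a modified Ichikado score, processes dual-channel antibody
    microarray intensities (rank-invariant lowess normalization, empirical
    Bayes moderated contrasts, Benjamini-Hochberg control), and provides the
    exact small-sample nonparametric test battery used for group comparisons.
    A calibrated synthetic-cohort generator with known ground truth makes
    every stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
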