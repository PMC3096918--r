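Package: fotmech
Title: Forced Oscillation Respiratory Mechanics and Bronchoprovocation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing low-frequency forced oscillation measurements of
    respiratory input impedance and methacholine bronchoprovocation studies in
    small animals. Implements the constant-phase model of respiratory impedance
    (airway resistance and inertance in series with a tissue compartment of
    damping and elastance), complex nonlinear least-squares fitting of measured
    impedance spectra, wave-tube (two-point) load impedance estimation from
    lateral pressure signals, plethysmographic end-expiratory lung volume
    computation via Boyle's law with box-impedance correction, dose-response
    ED50 estimation by linear interpolation, and the group statistics used in
    such studies (normality testing, one-way and mixed-design repeated-measures
    ANOVA, Student-Newman-Keuls post-hoc comparisons, grouped Pearson
    correlation). A synthetic-cohort generator provides ground-truth studies
    with the full measurement chain for validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    nortest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
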