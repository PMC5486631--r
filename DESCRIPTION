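Package: pulseheat
Title: Thermal Dosimetry for High-Frequency Nanosecond Pulsed Electric Field Ablation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled electric-field and bioheat simulation of two-needle
    pulsed electric field tumor ablation in liver tissue. Solves the
    quasi-static potential equation on a graded voxel grid with a stepped
    electroporation conductivity model, integrates the Pennes bioheat
    equation through a 100 microsecond nanosecond-pulse burst and a 1 s
    observation window, accumulates Arrhenius thermal damage, and provides
    multi-parameter sweeps over voltage, pulse width and repetition rate
    with closed-form temperature-law fitting and 44 degree Celsius
    safe-parameter envelope extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
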