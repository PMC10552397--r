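Package: meltshift
Title: Thermal Proteome Profiling Melting-Curve and Dose-Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of paired-TMT thermal proteome profiling (TPP)
    experiments. Implements a three-step normalization for
    temperature-range (TR) designs in which treatment and control samples
    share TMT 10plex labeling sets, sigmoidal melting-curve fitting with
    four- and three-parameter models, per-protein differential
    thermal-stability and abundance scoring (melting-point shifts,
    per-temperature significance, distance scores), compound
    concentration-range (CCR) dose-response fitting with pEC50/Hill
    estimation and pseudo-R-squared responder classification, and a
    CETSA immunoblot quantification path. A synthetic-data generator with
    known ground truth supports end-to-end testing and power/calibration
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
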