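Package: vmrscreen
Title: Scotopic Visual Motor Response Drug-Screen Analysis for Zebrafish
    Models of Retinal Degeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of scotopic visual motor response (VMR)
    assays used for phenotypic drug screening in larval zebrafish. Provides a
    generative model for 96-well per-second displacement traces (light-off
    startle bursts, batch and well-position effects, toxic wells), linear-model
    normalization for baseline activity, well intensity variation and batch
    effect, two-sample Hotelling's T-squared and a high-dimensional studentized
    max-type two-sample mean test with resampling calibration, the dual-criterion
    hit-calling funnel (replicate consistency at p > 0.9, difference from vehicle
    at p < 0.05 over 1-s and 30-s post-offset windows), and logistic
    dose-response fitting reporting pEC50/pIC50. Includes supporting contingency,
    Welch and ANOVA/FDR tests and a small command-line pipeline.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
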