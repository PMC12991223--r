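Package: vgctools
Title: Visual Grading Characteristics Analysis for Multi-Reader
    Multi-Case Observer Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "package.author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing ordinal image-quality ratings from
    multi-reader multi-case (MRMC) visual grading studies.  Implements
    visual grading characteristics (VGC) curves, the tie-corrected
    nonparametric AUC figure-of-merit with per-observer estimation and
    averaging, maximum-likelihood binormal curve fitting, fixed-reader
    paired-case bootstrap confidence intervals and significance tests
    against the null AUC of 0.5, a dose-area-product to effective-dose
    model with BMI-stratified summaries, and a seeded latent-variable
    generator of synthetic rating panels with known ground truth for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
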