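Package: karyomorph
Title: Karyomorphometry, Karyotype-Length Statistics and Flow-Cytometric
    Genome Size Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative karyotype analysis from per-metaphase
    chromosome arm measurements: arm ratios and Levan morphology classes,
    relative lengths, asymmetry index, karyotype length and formula,
    population summaries with coefficient-of-variation validation,
    Gaussian analysis of deviance across populations with iterative
    level pooling (compact letter display), genome-size estimation from
    fluorescence histograms against an internal standard, seeded synthetic
    data generators, and idiogram construction with SVG rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
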