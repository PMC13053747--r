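Package: lidwiper
Title: Lid-Wiper Biomarkers from Zernike Analysis of Corneal Epithelial
    Thickness Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the effect of upper-eyelid motion during blinking
    (the lid-wiper effect) on the corneal epithelium. Decomposes 5-mm-zone
    epithelial thickness maps into ANSI-convention Zernike polynomials by
    mask-aware least squares, derives population lid-wiper axes from the
    mean tilt and sign-flipped primary-coma vectors, and projects each
    eye's vectors onto those axes to obtain two scalar biomarkers: the
    lid-wiper gradient (um/mm) and the lid-wiper coma (um). Includes the
    accompanying statistical battery (normality-gated one-sample and
    paired tests with Bonferroni correction, root-sum-square aberration
    summaries, biomarker regressions, circular statistics and bivariate
    confidence ellipses), a laterality-aware map-processing pipeline, and
    a synthetic cohort generator for validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    MASS,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'zernike.R'
    'fit.R'
    'pipeline.R'
    'metrics.R'
    'stats.R'
    'synthetic.R'
    'cli.R'
    'lidwiper-package.R'
    'utils.R'
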