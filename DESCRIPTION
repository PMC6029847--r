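Package: collagenmech
Title: Multiscale Collagen Structure-Function Analysis for Fibrotic Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of multiscale collagen biomechanics in fibrotic lung
    tissue: elastic-modulus estimation from atomic force microscopy (AFM)
    micro- and nanoindentation force curves (Hertz sphere and Oliver-Pharr
    models), collagen fibril morphometry from height topography (D-period,
    diameter, swelling ratio), Young's modulus of quasi-spherical 3D cultures
    from parallel-plate compression (modified Hertzian sphere-between-plates
    model), biochemical normalisation (hydroxyproline to collagen, cross-link
    densities and ratios, solubility fractions, delta-delta-Ct expression),
    and the accompanying statistical layer (Welch/Mann-Whitney tests,
    Holm-Sidak adjustment, Dunnett and Dunn post hoc comparisons,
    missing-data multivariate-normal correlation by EM, four-parameter
    logistic dose-response fits). Includes seeded synthetic-data generators
    with ground-truth sidecars for every input class, used for recovery
    testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    minpack.lm,
    mvtnorm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
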