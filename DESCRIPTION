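Package: ctcoloc
Title: Spatial Colocalization of Cortical Thickness Development with
    Neurobiological Marker Maps
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Links lifespan cortical-thickness change maps, extracted from a
    normative trajectory grid, to parcellated molecular and cellular brain-atlas
    maps. Provides variogram-matched surrogate map generation for spatial-
    autocorrelation-preserving null inference, factor-analytic reduction of
    marker sets (minimum-residual extraction, promax rotation), sliding-window
    regression scans with empirical one-sided p-values and FDR families,
    dominance-analysis decomposition of explained variance with surrogate-null
    significance, regional influence (prediction-error difference) maps,
    developmental gene-expression period tests against non-brain null gene
    sets, and a subject-level longitudinal validation pipeline. A synthetic-data
    generator emulates every input with known ground truth so the full analysis
    runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
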