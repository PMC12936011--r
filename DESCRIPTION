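Package: caroSpectra
Title: Leaf Reflectance Indices and Ensemble Models for Maize Carotenoid
    Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Non-destructive estimation of maize leaf carotenoid content
    from visible/near-infrared reflectance spectra (400-1000 nm). Provides
    an S4 container for reflectance spectra joined to pigment measurements,
    spectrophotometric pigment equations and their algebraic inverses, a
    registry of classical and maize-specific carotenoid band-ratio indices
    (CAR1-CAR9), principal-component analysis with varimax rotation and
    Kaiser-Meyer-Olkin diagnostics for sensitive-band selection, linear
    index calibration with year-grouped validation and a six-metric error
    bundle (R2, RMSE, NRMSE, MAE, MBE, NSE), from-scratch regression-tree
    ensembles (reduced-error-pruning tree, bagging, random subspace,
    random forest) with cross-validation, and a synthetic study generator
    that emulates the statistical structure of field campaigns for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, data.table, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
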