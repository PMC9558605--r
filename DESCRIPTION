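Package: thzchem
Title: Chemometric Calibration of Terahertz Absorbance Spectra of Ternary Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the composition of ternary powder mixtures
    (caffeine, quinic acid, nicotinic acid in a polyethylene binder) from
    terahertz time-domain absorbance spectra. Provides a synthetic-spectra
    generator reproducing the simplex mixture design of the underlying
    experiment, a Mie-scattering baseline removal formulated as a penalized
    convex fit of xi*Qext(omega) to the spectral troughs, normalization and
    dimensionality-reduction stages (Z-score, min-max, PCA, factor analysis,
    ICA, LLE and modified LLE, NMF, isomap) fitted on training data only,
    five calibration model families (PLSR, SVR, MLP, 1-D CNN, gradient
    boosting) behind a uniform train/predict contract, and a grouped k-fold
    cross-validation engine reporting RMSEC/RMSEP with preprocessing-effect
    and linearity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    xgboost,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    yaml
Config/testthat/edition: 3
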