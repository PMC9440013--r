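Package: lipolfer
Title: Two-Parameter LFER Prediction of Lipid-Water Partition Coefficients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts storage-lipid-water (logKlw) and phospholipid-water
    (logKpw) partition coefficients of neutral organic chemicals from the
    octanol-water partition coefficient (logKow) and the dimensionless
    Henry's law constant (logKaw), using calibrated two-parameter linear
    free energy relationships (tp-LFERs). Ships a registry of eight
    published coefficient sets, ordinary-least-squares calibration with
    bootstrap standard errors, leave-one-out / k-fold / bootstrap
    cross-validation, applicability-domain assessment via regression
    influence diagnostics, PCA and correlation analyses of solute
    descriptor matrices, a synthetic-data generator emulating the
    statistical structure of the calibration data, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
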