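Package: cafspec
Title: Covering-Array Feature Selection for NIR Fermentation Chemometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for predicting pH and total soluble solids
    (TSS) during coffee fermentation from near-infrared (NIR) spectra.
    Provides spectral preprocessing (reflectance-to-absorbance conversion,
    Savitzky-Golay smoothing), single-response partial least squares
    regression via deterministic NIPALS, and three wavelength-selection
    strategies: regression (beta) coefficients, variable importance in
    projection (VIP), and covering-array feature selection (CAFS) built on
    greedy strength-t covering arrays. Includes a repeated K-fold
    cross-validation protocol with R-squared, RMSE and RPD metrics, a
    Kolmogorov-Smirnov normality statistic, and a synthetic fermentation
    spectra generator for end-to-end testing when laboratory data are
    unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
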