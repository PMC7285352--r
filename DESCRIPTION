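Package: lolichemo
Title: Chemometric Calibration of Loline Alkaloids and Fungal Biomass from
    Near-Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete near-infrared spectroscopy (NIRS) calibration
    workflow for quantifying loline alkaloids (N-acetylloline,
    N-acetylnorloline, N-formylloline and their sum) and in-planta fungal
    mycelium in endophyte-infected grasses. Implements spectral
    pre-treatments (standard normal variate, detrending, gap-segment
    derivatives with smoothing), principal-component outlier screening via
    the Mahalanobis H statistic, modified partial least squares (MPLS)
    regression with between-factor residual standardization, grouped
    cross-validation with two-round T-outlier elimination, the full suite
    of calibration statistics (RSQ, SEC, SECV, SEP, SEPc, BIAS, RPD), and a
    grid search over 400 candidate pre-treatment combinations. A synthetic
    spectra generator with known ground truth supports end-to-end testing
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
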