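Package: irsyn
Title: Immuno-Infrared Sensor Analysis of Alpha-Synuclein Misfolding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for immuno-infrared sensor (iRS) ATR-FTIR
    difference spectroscopy of alpha-synuclein misfolding in cerebrospinal
    fluid. Provides spectral input/output (CSV and JCAMP-DX), a calibrated
    synthetic-data generator for cohort-scale simulation, the spectral
    processing chain (averaging, water-vapor and baseline correction,
    difference spectra, Savitzky-Golay smoothing, Amide-I normalization),
    quality-control gates (Amide-I/II ratio, signal-to-noise), secondary
    structure read-outs (absolute and center-of-mass Amide-I maxima, the
    1656.0/1623.5 absorbance ratio, difference-band integrals), single and
    double-threshold (traffic-light) classification with confusion metrics,
    and cohort statistics (Mann-Whitney U, chi-square, covariate-adjusted
    logistic scoring with ROC/AUC and DeLong confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pROC,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
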