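Package: wnmr
Title: Benchtop Water-Proton NMR Relaxometry: CPMG Decay Correction,
    Fitting, and Interlaboratory Study Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing water-proton transverse relaxation
    (R2(1H2O)) measurements from benchtop time-domain NMR instruments.
    Reads CPMG echo-decay records in the CSV dialects produced by
    benchtop relaxometers (real-only or quadrature), corrects the three
    common low-field artifact classes (zero-order phase deviation,
    eddy-current transients from conductive vial caps, AC-line
    oscillations), fits the offset mono-exponential decay model to
    extract R2(1H2O), and aggregates per-sample rates into per-laboratory
    relaxivity calibrations, interlaboratory dispersion statistics
    (span, coefficient of variation), freeze/thaw outlier detection for
    aluminum-adjuvant suspensions, and zero-slope negative-control
    checks.  A synthetic multi-laboratory CPMG study generator with
    configurable lab profiles allows the complete analysis to run with
    no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
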