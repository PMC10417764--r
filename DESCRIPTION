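Package: hrvkit
Title: Heart Rate Variability Analysis of RR-Interval Tachograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the analysis of heart rate variability (HRV) from
    RR-interval (tachogram) series: reading, validation and artifact
    filtering of plain-text and CSV tachograms; time-domain statistics
    (SDNN, SDANN, RMSSD, pNN50, SDNN index); geometric measures (RR
    histogram, HRV triangular index, TINN); nonlinear measures (detrended
    fluctuation analysis, Poincare plot descriptors, approximate and sample
    entropy, rescaled-range Hurst exponent); time-frequency analysis of the
    evenly resampled tachogram (Welch power spectral density, short-time
    Fourier spectrogram, Morlet continuous wavelet spectrum, VLF/LF/HF band
    powers); seeded synthetic tachogram generators (Gaussian, bimodal,
    fractional Gaussian noise, modulated, cohort builders) for method
    validation; cohort comparison with Welch and paired t-tests; and
    flagging of parameter values against published normal ranges.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    pracma,
    signal,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
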