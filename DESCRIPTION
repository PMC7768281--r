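Package: bandratios
Title: Band Ratio Measures, Spectral Parameterization, and Simulated EEG Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying frequency band ratio measures (such as the
    theta/beta ratio) in neural power spectra. Provides a generative model of
    power spectra as a 1/f-like aperiodic component plus Gaussian periodic
    peaks, Welch spectral estimation from time series, band-ratio measures
    over canonical frequency bands, a spectral parameterization routine that
    separates periodic from aperiodic activity, single- and paired-parameter
    simulation sweeps, a synthetic resting-state EEG cohort generator with
    ground-truth spectral parameters, and bootstrap correlation statistics
    (Spearman confidence intervals and difference-of-correlation tests) for
    relating ratio measures to the spectral parameters that drive them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
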