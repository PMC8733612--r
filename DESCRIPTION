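Package: eispec
Title: Spectral and Criticality Biomarkers for Resting-State EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying excitation/inhibition-related biomarkers in
    multichannel resting-state EEG: high-resolution Welch power spectra,
    detrended fluctuation analysis (DFA) of narrowband amplitude envelopes,
    the functional excitation/inhibition ratio (fE/I), and aperiodic (1/f)
    spectral parameterization. Includes a full sensor-level preprocessing
    chain (FIR filtering, automated bad-channel detection, spherical-spline
    interpolation, average re-referencing, epoch-based artifact rejection,
    ICA-based ocular artifact removal), mass-univariate ANCOVA group
    statistics with an age covariate and Bonferroni correction, and a
    synthetic-cohort generator with ground-truth Hurst exponents,
    amplitude-fluctuation coupling and aperiodic slopes for validating the
    estimators.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    e1071,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
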