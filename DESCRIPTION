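Package: ergHill
Title: Light-Adapted ERG Waveform Analysis and Photopic Hill Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for light-adapted flash electroretinogram (ERG) cohort
    analysis: a calibrated simulator of flash-series ERG waveforms with
    clustered two-eye repeated measures, extraction of the standard a-wave,
    b-wave and photopic negative response (PhNR) waveform parameters,
    five-parameter photopic hill (log-Gaussian plus saturating) fitting of
    b-wave luminance-response curves, generalized estimating equation (GEE)
    group comparison with QIC model assessment, nonparametric pairwise
    flash-wise tests, and ROC-based discrimination of diagnostic groups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    sandwich,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
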