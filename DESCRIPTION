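Package: trggc
Title: Nonparametric Granger-Geweke Causality with Time-Reversal Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Frequency-resolved directed-influence (Granger-Geweke causality)
    estimation for multichannel trial-based time series, computed
    nonparametrically from multitaper cross-spectral density matrices via
    Wilson's spectral matrix factorization. Provides pairwise and conditional
    estimators, net and time-reversed (tr-GGC) testing variants, multivariate
    autoregressive (MVAR) network simulators, observation-corruption models
    (common reference, SNR imbalance, independent and mixed additive noise),
    scenario drivers that sweep corruption strength, and readers/writers for
    the trial-epoch MAT-file container used by the companion rat
    somatosensory-evoked-potential benchmark, including a synthetic
    SEP-like fixture generator.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
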