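Package: eegdvp
Title: Stochastic Duffing-van der Pol Oscillator Models of EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models single-channel resting EEG as the output of a pair of
    noise-driven, coupled Duffing-van der Pol oscillators. Provides an
    Euler-Maruyama simulator for the stochastic system, amplitude-threshold
    artifact detection with spectral gap repair, spectral and entropic
    feature extraction (band powers, binned Shannon entropy, sample
    entropy), average-mutual-information delay selection and time-delay
    embedding, multi-start bounded fitting of the oscillator parameters to
    a target block's features, group comparison of fitted parameters with
    multiple-comparison correction and power analysis, and a synthetic
    resting-EEG generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
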