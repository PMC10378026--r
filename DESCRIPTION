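Package: petd
Title: Permutation-Entropy Time-Delay Estimation of Intrinsic Timescales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the dominant intrinsic timescale of a sampled signal
    as the embedding delay at which permutation entropy attains its global
    minimum (PE-TD), alongside the established autocorrelation-window
    benchmark (ACW-0, first zero-crossing of the autocorrelation function,
    optionally in sliding windows). Includes ground-truth signal generators
    (a leaky integrate-and-fire neuron and the Mackey-Glass delay
    oscillator), a nonstationarity-robustness experiment based on
    concatenated stationary segments, parameter sweeps over the oscillator's
    feedback strength, nonlinearity and delay, channel-wise timescale maps
    for multichannel recordings, and group-level statistics (Spearman map
    correlation, bootstrap and Fisher-z tests for a difference of
    correlations, Wilcoxon rank-sum). A command-line interface exposes the
    estimators, simulators and experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
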