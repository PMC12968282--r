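Package: neuroq
Title: Neural Complexity from EEG Inter-Event Intervals via Nonextensive Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the complexity of EEG-like signals with Tsallis
    nonextensive statistics. Sub-threshold amplitude events are extracted
    per channel (threshold at -1 SD from the mean of the negative part of
    the signal), inter-event intervals are binned into an empirical
    probability distribution, and a four-parameter q-exponential
    probability function is fitted by bounded multi-start least squares.
    The entropic index q of the fitted law indexes complexity, with the
    Boltzmann-Gibbs exponential recovered in the q -> 1 limit as the null
    model. Includes Tsallis and Boltzmann-Gibbs entropy functionals, a
    logistic-map chaotic test-signal generator, a seeded q-exponential
    interval sampler, surrogate EEG-like signal synthesis with planted
    ground truth, delimited-text and 16-bit EDF signal IO, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
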