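Package: stnets
Title: Spike Timing Networks from Multineuron Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extracts spike timing networks, groups of neurons with
    consistent between-neuron spike time delays forming spike sequences,
    from multi-trial multineuron spike recordings. Binary spike trains are
    convolved with untapered complex exponentials at a ladder of
    frequencies, trial-wise cross spectra are formed, optionally
    normalized neuron-wise and trial-wise, and decomposed by alternating
    least squares into rank-one Hermitian components, each described by a
    neuron profile, a circular per-neuron time profile in seconds, a
    frequency profile, and a trial profile. Includes a spike-sequence
    simulator with Poisson noise, spike jitter and spike deletion, a
    split-half reliability procedure for choosing the number of networks,
    recovery statistics against simulated ground truth, and continuous
    cross-correlograms for validating extracted time delays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
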