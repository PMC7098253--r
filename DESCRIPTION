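Package: mwpneuro
Title: Mean Wavelet Power and Comparator Neural Features for Intracortical Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts mean wavelet power (MWP) neural features from raw
    multielectrode-array voltage recordings by multilevel 'db4' discrete
    wavelet decomposition in 100 ms bins, alongside the standard comparator
    features used in intracortical brain-computer interfaces: threshold
    crossings (TC), low-pass local field potentials (LFP) and band-pass
    multi-unit activity (MUA). Provides the shared post-processing chain
    (causal smoothing, windowed baseline subtraction, train-block
    standardization), signal-to-noise and chronic signal-strength stability
    summaries, spatial and inter-signal correlation analyses, and per-movement
    RBF-SVM decoding of cued hand movements. A simulator generates cue
    schedules and synthetic recordings with cue-locked spiking, spatially
    correlated low-frequency oscillations and optional chronic amplitude
    decay, so every analysis can be exercised without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
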