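Package: somnoscore
Title: Automated Behavioral-State Scoring of Rodent EEG/EMG Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated wake/NREM/REM scoring of chronic rodent
    electrophysiological recordings in 4 s epochs. Computes Welch
    band-limited power and EMG features per epoch, trains a small ensemble
    of feed-forward neural networks on a sparsely hand-scored training set
    (about 2.6% of a day), flags low-certainty epochs for optional manual
    rescoring, applies heuristic hypnogram smoothing rules, gates scoring on
    EMG signal quality, and derives standard sleep parameters
    (state-dependent spectra, slow-wave-activity timecourse, state durations
    and bout statistics). Includes a seeded synthetic-recording generator
    with ground-truth hypnograms for end-to-end validation.
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
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
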