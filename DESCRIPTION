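Package: esporterp
Title: Expertise Biomarkers from Oddball EEG and Cognitive Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An analysis pipeline for two-group (professional versus novice
    video-game player) expertise studies combining oddball-paradigm EEG and
    cognitive testing. Provides a calibrated synthetic-data generator
    (epoched multi-channel EEG with P200/N200/P300 components, 1/f
    background and alpha oscillations, plus reaction-time and visual-search
    trial logs), FIR filtering and artifact preprocessing, ERP component
    measurement with fractional-area latency, variational mode decomposition
    and Hilbert-Huang spectrograms, canonical polyadic tensor decomposition
    with orthogonal spatial factors, and a shared statistical engine
    (permutation Welch t-tests, Hedges' g, Mann-Whitney U, threshold-free
    cluster enhancement over 1-D, 2-D and channel-graph domains, and
    Spearman correlation maps).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
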