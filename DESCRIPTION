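Package: tvcgbeat
Title: Inter-Patient ECG Heartbeat Classification with the Temporal Vectorcardiogram
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Heartbeat classification for two-lead ECG recordings under the
    inter-patient evaluation paradigm. Beats are represented as a temporal
    vectorcardiogram (the two leads plus time as a third axis) and described by
    degree-based complex-network features extracted over an evolving distance
    threshold, alongside reference morphological, interval and Haar-wavelet
    feature sets. Classification uses a class-weighted RBF support vector
    machine; complex-network parameters, class weights and a wrapper feature
    mask are tuned by continuous and binary particle swarm optimization.
    Includes AAMI-style per-class sensitivity, positive predictivity and
    false-positive-rate metrics, the canonical MIT-BIH inter-patient record
    partitions, a seeded synthetic two-lead beat generator, and readers for
    WFDB-style and CSV record formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    graphics,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
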