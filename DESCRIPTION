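Package: holofm
Title: Holographic Feature Maps for EEG Emotion Recognition with Channel Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for valence/arousal/dominance emotion
    recognition from multichannel EEG. Trials are decomposed into
    delta/theta/alpha/beta/gamma subbands with a db5 discrete wavelet
    transform; nine per-subband signal characteristics (band power,
    differential entropy, Higuchi fractal dimension, Hjorth parameters,
    RMS, peak-to-peak, mean Welch PSD) are rendered as two-dimensional
    holographic feature maps by off-axis point-source computer-generated
    holography; channels are ranked by ReliefF or neighborhood component
    analysis and the top channels retained; small per-characteristic
    convolutional networks extract features that are fused and classified
    with a polynomial-kernel support vector machine under stratified
    ten-fold cross-validation. Ships a seeded synthetic EEG generator with
    class-conditional band-power structure so the whole pipeline is
    testable without restricted datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    e1071,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
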