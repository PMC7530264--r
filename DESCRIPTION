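Package: eegheatmap
Title: EEG Heat-Map Imaging and Texture-Based Alcoholism Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Transforms multichannel EEG recordings into 8-bit grayscale
    heat-map images (channels as fixed-width pixel blocks, time down the
    rows) and classifies alcoholic versus control subjects from image
    texture. Provides variance-based channel selection, amplitude
    clipping at +/-73.3 microvolts, min-max quantization to 0-255, image
    composition and PNG round-tripping; equation-faithful gray-level
    co-occurrence (14 Haralick statistics), multi-scale local binary
    pattern and Hu invariant-moment descriptors; a headless
    transfer-learning feature-extraction contract with a backbone
    dimension registry; and a classifier evaluation harness (naive
    Bayes, k-NN, MLP, random forest, SVM) with random hyperparameter
    search, repeated stratified 80/20 splits and macro-averaged
    accuracy, precision, recall and F1. A seeded synthetic EEG generator
    with band-limited class signals and artifact spikes makes the whole
    pipeline testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    e1071,
    ranger,
    nnet,
    class,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
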