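Package: afcnn
Title: Compressed Channel-Attention Convolutional Networks for Atrial
    Fibrillation Detection from Interbeat Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects atrial fibrillation from windows of 30 consecutive
    RR (or PPG beat-to-beat) intervals with small one-dimensional
    convolutional neural networks whose capacity is compressed through
    channel attention.  Provides readers and writers for WFDB-style beat
    and rhythm annotations, episode extraction and window segmentation
    with class balancing, squeeze-excitation and attention-as-activation
    modules with ReLU, Swish and sine activations, minibatch
    stochastic-gradient training, confusion-matrix evaluation with an
    attention-ablation harness, k-fold cross-validation, learnable
    parameter accounting, one-dimensional Grad-CAM saliency, and a
    synthetic RR-interval generator so the whole pipeline is testable
    without any physiological recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
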