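Package: semgpose
Title: Cross-Trial Surface-EMG Gesture Recognition via Mutual-Information
    Pretraining and Cross-Modal Knowledge Distillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-trial gesture recognition from sparse multichannel
    surface electromyography (sEMG). Implements a dual-stream convolutional
    network with multi-head self-attention for windowed sEMG classification,
    and a two-stage training scheme: stage one learns trial-invariant
    representations by maximizing mutual information between windows sampled
    at the same time step of different trials (InfoNCE lower bound) while
    disentangling gesture-relevant from trial-relevant factors (CLUB upper
    bound with a learned Gaussian variational conditional); stage two
    fine-tunes the encoder under cross-modal knowledge distillation from a
    hand-pose teacher network. Includes a synthetic sEMG-trial simulator with
    aligned quaternion hand-pose streams, NinaPro-style preprocessing
    (Butterworth/RMS filtering, sliding-window segmentation, mu-law
    normalization), cross-trial evaluation with per-subject accuracies,
    an exact Wilcoxon signed-rank test, MAT-file import/export, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
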