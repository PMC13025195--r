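Package: ictd
Title: Dual-View Eye-Movement Emotion Classification with a CNN-Transformer
    and Cosine-Similarity Deep CCA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the ICTD model for emotion classification from
    eye-movement recordings: gaze and pupil feature views are encoded by
    multi-scale CNN-transformer branches whose feedforward sublayer is an
    incremental feature feedforward network (partial convolution, channel
    split, cross-channel gating), and the two views are aligned with a
    cosine-similarity deep canonical correlation objective trained jointly
    with cross-entropy. Includes raw gaze preprocessing, I-VT event
    detection, fixation/saccade/pupil feature extraction with one-way ANOVA
    screening, Russell-model label mapping, subject-independent k-fold
    cross-validation, an ablation harness, a synthetic dual-view data
    generator with known latent structure, and a closed-form linear CCA
    oracle. A small reverse-mode automatic-differentiation engine powers
    training on CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
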