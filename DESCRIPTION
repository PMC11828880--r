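Package: noisytools
Title: Robust Multi-Label Surgical Tool Classification from Noisy Clip-Level Labels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A systematic methodology for training robust multi-label
    surgical-tool classifiers from video-frame data whose clip-level labels are
    noisy, leaky and long-tail imbalanced. Provides a clip-structured synthetic
    scene generator with hidden ground truth; preprocessing (label
    standardisation, keyframe extraction, black-frame handling,
    segmentation-based dynamic cropping, label extrapolation); stratified
    splitting by label combination and reciprocal-log weighted sampling; a
    four-member classifier ensemble with a weighted ensemble loss, max-prob and
    mean-logit-sigmoid aggregation and top-3 decisions; an active-learning
    label-cleaning loop with loss-based epistemic scoring; student-teacher
    self-training with label smoothing and weighted-data-loader fine-tuning;
    and a macro-metric evaluation harness with one-way ANOVA, Kruskal-Wallis
    and Tukey HSD method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
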