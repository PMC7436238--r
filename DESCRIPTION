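Package: pullbacknet
Title: Temporally Stable Tissue Classification for Endoscopic Pullback Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-by-frame tissue classification of esophageal pullback
    videos (stomach, transition Z-line, Barrett, transition squamous,
    squamous) with a convolutional feature extractor and four
    interchangeable classifier heads: fully connected, fully connected
    with a causal output-averaging filter, two-layer LSTM and two-layer
    GRU. Includes the class- and case-balanced sequence sampler,
    per-sequence-constant affine augmentation, cyclic cosine learning-rate
    schedule and Adam training loop; transition-tolerant label accuracy
    through a predicted-to-acceptable-label correspondence map;
    a label-switch stability metric; per-patient-normalized confusion
    matrices; patient-level k-fold cross-validation with paired Wilcoxon
    signed-rank comparison; and a synthetic pullback-video generator that
    emulates the fixed anatomical class order, gradual appearance
    transitions, class imbalance and sporadic non-informative frames of
    real procedures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    png,
    yaml,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
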