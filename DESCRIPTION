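Package: bremtool
Title: Brain Rhythm Entropy Matrix Analysis for EEG Emotion Recognition
Version: 0.1.0
Authors@R:
    person("BREM", "Maintainers", email = "maintainers@bremtool.org", role = c("aut", "cre"))
Description: Resource-efficient multi-entropy fusion for EEG-based emotion
    recognition. Decomposes single-channel EEG into the five canonical brain
    rhythms (delta, theta, alpha, beta, gamma) with a four-level discrete
    wavelet transform, extracts six entropy features (approximate, fuzzy,
    sample, permutation, singular-spectrum and spectral entropy) per rhythm,
    and fuses them into a Brain Rhythm Entropy Matrix (BREM). Emotional state
    is classified by comparing a test BREM against one positive and one
    negative template under dynamic time warping, mutual information,
    Spearman rank correlation or Jaccard similarity, with an exhaustive
    leave-one-out template-cycling evaluation protocol, channel/segment grid
    search, ANOVA feature screening, and a synthetic two-class EEG generator
    for fully self-contained validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
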