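Package: braillemvpa
Title: Cross-Hand Decoding of Braille Letter Representations from Neural Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate pattern analysis of braille letter representations in the
    visually deprived brain: pairwise linear support-vector-machine decoding of
    letter identity within and across the reading hand, time-resolved (EEG-like)
    and spatially resolved (fMRI-like ROI and searchlight) variants, pseudo-trial
    averaging with multivariate noise normalization, representational similarity
    analysis against behavioral letter-similarity ratings, and bootstrap inference
    on decoding onset latencies. Ships a synthetic-data generator that emulates the
    8-letter x 2-hand experimental design with separable hand-dependent (sensory)
    and hand-independent (perceptual) letter codes, so the full pipeline is
    testable end to end without any neuroimaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
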