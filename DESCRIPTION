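Package: rrsa
Title: Regression-Based Representational Similarity Analysis for EEG Epochs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-resolved and cross-temporal representational similarity
    analysis (RSA) of multichannel EEG epochs, decomposed by per-sample
    ordinary least squares into word-specific, semantic, and orthographic-form
    components. Builds pairwise predictor tables from a sentence lexicon using
    Lin taxonomy similarity and normalized Levenshtein edit similarity, computes
    pairwise spatial-pattern correlation series and temporal-generalization
    matrices, and provides the inferential layer used in EEG prediction studies:
    chance-level estimation, Benjamini-Yekutieli window detection, cluster-mass
    permutation tests, and jack-knife latency comparisons. A synthetic-data
    generator plants known representational structure so the full pipeline can
    be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    signal,
    stringi,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
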