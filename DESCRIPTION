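Package: lexalign
Title: Cross-Modal Alignment and Learnability of Early-Acquired Words
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the category structure of word representations in
    visual and linguistic embedding spaces and relates it to word
    learnability. Provides within-category variability and between-category
    discriminability metrics, a rank-based cross-modal alignment-strength
    statistic with a permutation null (relative alignment strength),
    exemplar-aggregation simulations that model prototype formation as a
    learner accumulates instances, a synthetic generator for
    category-structured bimodal embedding systems with known ground truth,
    and a gradient-boosted regression of age of acquisition on the computed
    features with exact tree-Shapley attributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
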