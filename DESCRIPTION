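Package: pairforage
Title: Foraging-Strategy Similarity Within Seabird Breeding Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether breeding partners in a central-place
    foraging seabird colony are more similar or more dissimilar in their
    foraging phenotype than randomized pairs. Provides a synthetic colony
    generator with configurable within-pair trait (dis)assortment, GPS track
    regularization with a four-state hidden Markov model activity classifier
    (colony, diving, flying, swimming), dive detection and foraging-trip
    segmentation with per-bird behavioural metrics, kernel utilization
    distributions with volume contours and Bhattacharyya affinity overlap,
    and pair-level inference: an exhaustive female-by-male cross-pair table,
    weighted logistic regression with AICc model selection, and a
    matching-permutation significance test that respects the one-mate-per-bird
    constraint.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
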