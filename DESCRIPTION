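Package: gasvm
Title: Genetic Algorithm / SVM Wrapper Feature Selection for Expression
    Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biomarker discovery from two-class gene expression matrices with a
    wrapper feature selector that evolves small gene subsets by a genetic
    algorithm scored through internally cross-validated Gaussian-kernel support
    vector machines. Includes differential-expression prefiltering (Welch t-test
    with Benjamini-Hochberg false discovery rate control and fold-change
    ranking), subject-grouped stratified cross-validation folds, baseline
    single-gene rankers (MDL-discretized information gain and random-forest
    permutation importance) with average-rank aggregation, joint-occurrence
    statistics for gene pairs across repeated selector runs (chi-square tests,
    over/under-representation scores and paired SVM accuracy gains), mutual
    information redundancy profiling, hypergeometric over-representation
    analysis against reference gene lists, and a synthetic two-class expression
    generator with planted markers, redundancy blocks and subject-level
    correlation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    randomForest,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
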