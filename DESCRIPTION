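Package: geneFilterDE
Title: Hybrid Filter and Binary Differential-Evolution Gene Selection
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Two-stage feature selection for high-dimensional gene-expression
    data. Six classifier-independent filter methods (information gain, gain
    ratio, chi-squared, Gini gain, Pearson correlation, Relief) score and rank
    genes; the top fraction (5 percent by default) is retained, and a binary
    differential-evolution search then minimises the stratified
    cross-validated misclassification rate of a chosen classifier over
    feature subsets of the reduced matrix. Includes confusion-matrix based
    evaluation with macro-averaged multiclass metrics and per-class
    false-positive/false-negative rates, a seeded synthetic microarray
    generator with planted informative and redundant genes, and an
    end-to-end pipeline with reproducible seed derivation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    S4Vectors,
    class,
    e1071,
    rpart,
    randomForest,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, GeneExpression, Microarray
RoxygenNote: 7.3.3
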