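# geneFilterDE

Two-stage gene selection for high-dimensional expression data: six
classifier-independent **filter** scorers rank the genes and keep the top
5%, then a **binary differential evolution** (DE) searches feature subsets
of the reduced matrix, minimising the stratified cross-validated
misclassification rate of a chosen classifier. It is aimed at analysts
working with microarray-scale data — tens of samples, thousands of genes,
2–5 classes — who need a reproducible, seeded implementation of the
hybrid filter + wrapper recipe with a full multiclass evaluation suite.

## Method

**Stage 1 (filter).** Each gene *A* is scored against the class label *S*
with one of:

- information gain
  `IG(S,A) = H(S) − Σ_v (|S_v|/|S|) H(S_v)`, `H(S) = −Σ_j p_j log2 p_j`
- gain ratio `IGR = IG / SplitInfo` (0 when the gene is constant)
- chi-squared `Σ_ij (O_ij − E_ij)² / E_ij` over the r-bins × c-classes table
- Gini gain, the impurity analogue of IG with `Gini(S) = 1 − Σ_j p_j²`
- absolute Pearson correlation with the integer-coded labels
- Relief: range-scaled nearest-hit / nearest-miss distance differences

Continuous genes are discretized into `r = 10` equal-width bins for the
entropy/contingency family. Genes are ranked (ties by index) and
`round_half_up(0.05 · m)` of them are kept — reproducing the benchmark
reductions 5597→280, 6129→306, 12600→630, 24481→1224.

**Stage 2 (wrapper).** Over 0/1 masks of the reduced genes, binary DE
iterates mutation (difference vector of two partners, ones forced into a
third), binomial crossover (`CR = 0.9`, one forced coordinate), and greedy
selection on the fitness
`misclassification rate = 1 − pooled stratified k-fold accuracy`.
The final mask is evaluated with pooled stratified 10-fold CV: accuracy,
per-class and macro recall / precision / F-measure, per-class and macro
FPR / FNR.

A seeded synthetic generator plants informative genes (class means spaced
`effect·σ` apart) and correlated redundant blocks, so the whole pipeline
is testable against known ground truth.

## Worked example

```r
library(geneFilterDE)

g   <- generateDataset(syntheticSpec(seed = 7))   # 60 samples x 600 genes
cfg <- pipelineConfig(filter = "ig",
                      de = deConfig(populationSize = 30, maxGenerations = 40),
                      evalClassifiers = list(classifierSpec("knn")),
                      seed = 7)
rep <- runHybrid(g$dataset, cfg)
print(rep)
#> Hybrid filter-DE run report
#>   input: 60 samples x 600 features, 2 classes
#>   filter: ig -> 30 features retained (top 5.0%)
#>   DE: 22 features selected, fitness 0.0000 (1230 evaluations)
#>   knn 10-fold accuracy: 100.00%

recoveryReport(rep$finalMask, g$truth)
#> $precision
#> [1] 0.8636364
#> $recallInformative
#> [1] 0.8666667
```

The report reads: information gain kept the 30 highest-ranked of 600
genes; DE then selected 22 of those 30 with a cross-validated
misclassification rate of 0; pooled 10-fold kNN evaluation of the final
22-gene signature is 100% accurate. Against the planted truth, 86% of
the selected genes carry real signal and 13 of the 15 planted informative
genes are represented (themselves or a correlated surrogate). Note the
evaluation reuses the samples used for selection (the original protocol)
and is optimistically biased; `runHybrid()` warns about this.

A command-line wrapper with `simulate`, `rank`, `pipeline` and `evaluate`
subcommands is installed at
`system.file("scripts", "genefilter-de.R", package = "geneFilterDE")`.

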