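#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Expression dataset with class labels
#'
#' `ExpressionDataset` is the central container of the package: a
#' \linkS4class{SummarizedExperiment} holding a real-valued expression matrix
#' (features in rows, samples in columns, following Bioconductor convention)
#' together with one categorical class label per sample stored in
#' `colData()$class_label`.  All selection and classification code accesses
#' the data through [exprsMatrix()], which returns the transposed
#' samples-by-features matrix used by the statistical machinery.
#'
#' Validity requires: a finite numeric matrix, unique feature and sample
#' identifiers, and at least two classes among the labels.
#'
#' @slot .
#'   See \linkS4class{SummarizedExperiment}; the label factor lives in
#'   `colData()$class_label` with levels in first-appearance order.
#'
#' @seealso [ExpressionDataset()] the constructor, [readExpressionTable()],
#'   [subsetFeatures()]
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  m <- SummarizedExperiment::assay(object, "exprs")
  if (!is.numeric(m))
    msg <- c(msg, "expression matrix must be numeric")
  else if (!all(is.finite(m)))
    msg <- c(msg, "expression matrix contains non-finite values")
  if (anyDuplicated(rownames(m)))
    msg <- c(msg, "duplicated feature identifiers")
  if (anyDuplicated(colnames(m)))
    msg <- c(msg, "duplicated sample identifiers")
  lab <- SummarizedExperiment::colData(object)$class_label
  if (is.null(lab)) {
    msg <- c(msg, "colData must contain a 'class_label' column")
  } else {
    if (length(lab) != ncol(m))
      msg <- c(msg, "one label per sample required")
    if (nlevels(droplevels(factor(lab))) < 2)
      msg <- c(msg, "at least two classes are required")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param exprs numeric matrix with **samples in rows** and features in
#'   columns (the package's working orientation; it is transposed into the
#'   underlying SummarizedExperiment).
#' @param labels categorical vector of length `nrow(exprs)`; coerced to a
#'   factor whose levels follow first-appearance order.
#' @param featureIds,sampleIds identifiers; default to the dimnames of
#'   `exprs` or generated `f1..fm` / `s1..sn`.
#' @return a validated [ExpressionDataset-class] object.
#' @examples
#' x <- matrix(rnorm(20), nrow = 4)
#' d <- ExpressionDataset(x, labels = c("a", "a", "b", "b"))
#' nFeatures(d)
#' @export
ExpressionDataset <- function(exprs, labels,
                              featureIds = colnames(exprs),
                              sampleIds = rownames(exprs)) {
  exprs <- as.matrix(exprs)
  if (is.null(featureIds)) featureIds <- paste0("f", seq_len(ncol(exprs)))
  if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(nrow(exprs)))
  labels <- as.character(labels)
  lab <- factor(labels, levels = unique(labels))
  a <- t(exprs)
  dimnames(a) <- list(as.character(featureIds), as.character(sampleIds))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = a),
    colData = S4Vectors::DataFrame(class_label = lab, row.names = colnames(a)))
  new("ExpressionDataset", se)
}

#' @describeIn ExpressionDataset samples-by-features expression matrix
#' @param x an `ExpressionDataset`
#' @param ... unused
#' @export
setMethod("exprsMatrix", "ExpressionDataset", function(x, ...)
  t(SummarizedExperiment::assay(x, "exprs")))

#' @describeIn ExpressionDataset per-sample class labels (factor)
#' @export
setMethod("classLabels", "ExpressionDataset", function(x, ...)
  SummarizedExperiment::colData(x)$class_label)

#' @describeIn ExpressionDataset ordered unique class names
#' @export
setMethod("classNames", "ExpressionDataset", function(x, ...)
  levels(SummarizedExperiment::colData(x)$class_label))

#' @describeIn ExpressionDataset feature identifiers
#' @export
setMethod("featureIds", "ExpressionDataset", function(x, ...) rownames(x))

#' @describeIn ExpressionDataset sample identifiers
#' @export
setMethod("sampleIds", "ExpressionDataset", function(x, ...) colnames(x))

#' @describeIn ExpressionDataset number of features (genes)
#' @export
setMethod("nFeatures", "ExpressionDataset", function(x) nrow(x))

#' @describeIn ExpressionDataset number of samples
#' @export
setMethod("nSamples", "ExpressionDataset", function(x) ncol(x))

#' @describeIn ExpressionDataset number of classes
#' @export
setMethod("nClasses", "ExpressionDataset", function(x)
  length(classNames(x)))

setMethod("show", "ExpressionDataset", function(object) {
  cat("ExpressionDataset:", nSamples(object), "samples x",
      nFeatures(object), "features,", nClasses(object), "classes (",
      paste(classNames(object), collapse = ", "), ")\n")
})

#' Per-feature filter scores
#'
#' Scores produced by one of the six filter methods.  Scores are
#' sign-normalised so that larger is always better.
#'
#' @slot method scoring method name (`ig`, `igr`, `chsqr`, `cr`, `gind`,
#'   `relief`)
#' @slot scores numeric vector, one finite score per feature
#' @slot featureIds feature identifiers, parallel to `scores`
#' @export
setClass("FeatureScores",
         representation(method = "character", scores = "numeric",
                        featureIds = "character"))

setValidity("FeatureScores", function(object) {
  msg <- character()
  if (length(object@method) != 1L)
    msg <- c(msg, "method must be a single string")
  if (!all(is.finite(object@scores)))
    msg <- c(msg, "scores must be finite")
  if (length(object@featureIds) != length(object@scores))
    msg <- c(msg, "featureIds and scores lengths differ")
  if (length(msg)) msg else TRUE
})

FeatureScores <- function(method, scores, featureIds = NULL) {
  if (is.null(featureIds)) featureIds <- paste0("f", seq_along(scores))
  new("FeatureScores", method = method, scores = as.numeric(scores),
      featureIds = as.character(featureIds))
}

#' @describeIn FeatureScores the numeric score vector
#' @param x a `FeatureScores`
#' @export
setMethod("featureScores", "FeatureScores", function(x) {
  s <- x@scores
  names(s) <- x@featureIds
  s
})

setMethod("show", "FeatureScores", function(object) {
  cat("FeatureScores <", object@method, ">: ", length(object@scores),
      " features, range [", format(min(object@scores), digits = 4), ", ",
      format(max(object@scores), digits = 4), "]\n", sep = "")
})

#' Feature ranking derived from filter scores
#'
#' @slot order integer permutation of `1..m`: feature indices sorted by
#'   decreasing score, ties broken by ascending feature index
#' @slot scores the [FeatureScores-class] the ranking was built from
#' @export
setClass("FeatureRanking",
         representation(order = "integer", scores = "FeatureScores"))

setValidity("FeatureRanking", function(object) {
  m <- length(object@scores@scores)
  if (length(object@order) != m ||
      !identical(sort(object@order), seq_len(m)))
    return("order must be a permutation of 1..m")
  s <- object@scores@scores[object@order]
  if (is.unsorted(-s)) return("scores must be non-increasing along order")
  TRUE
})

#' @describeIn FeatureRanking the rank order (best feature first)
#' @param x a `FeatureRanking`
#' @export
setMethod("rankOrder", "FeatureRanking", function(x) x@order)

#' @describeIn FeatureRanking scores of the underlying `FeatureScores`
#' @export
setMethod("featureScores", "FeatureRanking", function(x)
  featureScores(x@scores))

setMethod("show", "FeatureRanking", function(object) {
  cat("FeatureRanking over", length(object@order), "features; top:",
      paste(utils::head(object@scores@featureIds[object@order], 5),
            collapse = ", "), "...\n")
})

#' Differential-evolution search configuration
#'
#' Defaults follow the published setting for the binary search: population
#' size 50 and crossover rate 0.9.  The mutation factor `F` only enters the
#' classical continuous operator ([mutateContinuous()]); the binary
#' difference-vector rules do not use it.
#'
#' @slot populationSize number of individuals P (>= 4)
#' @slot crossoverRate per-position probability CR of inheriting the mutant
#'   bit, in `[0, 1]`
#' @slot mutationFactor F for the continuous reference operator, in `[0, 1]`
#' @slot maxGenerations generation budget G (0 evaluates only the initial
#'   population)
#' @slot seed integer RNG seed; the whole search is reproducible given it
#' @slot earlyStop stop when the best fitness reaches 0 or has not improved
#'   for `patience` generations (disabled by default)
#' @slot patience no-improvement window for `earlyStop`
#' @export
setClass("DEConfig",
         representation(populationSize = "integer", crossoverRate = "numeric",
                        mutationFactor = "numeric", maxGenerations = "integer",
                        seed = "integer", earlyStop = "logical",
                        patience = "numeric"))

setValidity("DEConfig", function(object) {
  msg <- character()
  if (object@populationSize < 4L)
    msg <- c(msg, "populationSize must be >= 4 (three distinct partners plus the target)")
  if (object@crossoverRate < 0 || object@crossoverRate > 1)
    msg <- c(msg, "crossoverRate must be in [0, 1]")
  if (object@mutationFactor < 0 || object@mutationFactor > 1)
    msg <- c(msg, "mutationFactor must be in [0, 1]")
  if (object@maxGenerations < 0L)
    msg <- c(msg, "maxGenerations must be >= 0")
  if (object@patience < 1)
    msg <- c(msg, "patience must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname DEConfig-class
#' @param populationSize,crossoverRate,mutationFactor,maxGenerations,seed,earlyStop,patience
#'   see the class slots
#' @return a validated `DEConfig`
#' @examples
#' deConfig(populationSize = 20, maxGenerations = 50, seed = 7)
#' @export
deConfig <- function(populationSize = 50L, crossoverRate = 0.9,
                     mutationFactor = 0.5, maxGenerations = 100L,
                     seed = 1L, earlyStop = FALSE, patience = Inf) {
  new("DEConfig", populationSize = as.integer(populationSize),
      crossoverRate = as.numeric(crossoverRate),
      mutationFactor = as.numeric(mutationFactor),
      maxGenerations = as.integer(maxGenerations), seed = as.integer(seed),
      earlyStop = as.logical(earlyStop), patience = as.numeric(patience))
}

#' Result of a differential-evolution run
#'
#' @slot bestMask best 0/1 feature mask ever evaluated
#' @slot bestFitness its fitness (misclassification rate, in `[0, 1]`)
#' @slot generationsRun generations actually executed
#' @slot history best-so-far fitness after initialisation and after each
#'   generation (non-increasing by construction)
#' @slot evaluations number of fitness-function calls made
#' @export
setClass("DEResult",
         representation(bestMask = "integer", bestFitness = "numeric",
                        generationsRun = "integer", history = "numeric",
                        evaluations = "integer"))

setValidity("DEResult", function(object) {
  msg <- character()
  if (!all(object@bestMask %in% c(0L, 1L)))
    msg <- c(msg, "bestMask must be 0/1")
  if (sum(object@bestMask) < 1L)
    msg <- c(msg, "bestMask must be non-empty")
  if (length(object@history) &&
      (is.unsorted(-object@history) ||
       object@bestFitness != object@history[length(object@history)]))
    msg <- c(msg, "history must be non-increasing and end at bestFitness")
  if (length(msg)) msg else TRUE
})

#' @describeIn DEResult best mask found
#' @param x a `DEResult`
#' @export
setMethod("bestMask", "DEResult", function(x) x@bestMask)

#' @describeIn DEResult fitness of the best mask
#' @export
setMethod("bestFitness", "DEResult", function(x) x@bestFitness)

#' @describeIn DEResult best-so-far fitness trajectory
#' @export
setMethod("fitnessHistory", "DEResult", function(x) x@history)

setMethod("show", "DEResult", function(object) {
  cat("DEResult:", sum(object@bestMask), "of", length(object@bestMask),
      "features selected; fitness", format(object@bestFitness, digits = 4),
      "after", object@generationsRun, "generations (",
      object@evaluations, "evaluations )\n")
})

#' Classifier specification
#'
#' Names one of the five supported learners with its hyperparameters:
#' `knn` (k nearest neighbours, `k = 3`), `nb` (Gaussian naive Bayes),
#' `dt` (CART decision tree), `rf` (random forest, `ntree = 100`),
#' `svm` (linear-kernel support vector machine).
#'
#' @slot name one of `knn`, `nb`, `dt`, `rf`, `svm`
#' @slot params named list of hyperparameter overrides
#' @slot seed seed for stochastic learners (random forest, kNN tie-breaks)
#' @export
setClass("ClassifierSpec",
         representation(name = "character", params = "list",
                        seed = "integer"))

setValidity("ClassifierSpec", function(object) {
  if (!object@name %in% c("knn", "nb", "dt", "rf", "svm"))
    return(sprintf("unknown classifier '%s'", object@name))
  TRUE
})

#' @rdname ClassifierSpec-class
#' @param name classifier name
#' @param ... hyperparameter overrides (e.g. `k = 1` for knn,
#'   `ntree = 200` for rf)
#' @param seed seed for stochastic learners
#' @examples
#' classifierSpec("knn", k = 1)
#' @export
classifierSpec <- function(name = c("knn", "nb", "dt", "rf", "svm"), ...,
                           seed = 1L) {
  name <- match.arg(name)
  defaults <- switch(name,
    knn = list(k = 3L),
    rf = list(ntree = 100L),
    svm = list(kernel = "linear"),
    list())
  params <- utils::modifyList(defaults, list(...))
  new("ClassifierSpec", name = name, params = params, seed = as.integer(seed))
}

setMethod("show", "ClassifierSpec", function(object) {
  p <- if (length(object@params))
    paste(names(object@params), unlist(lapply(object@params, format)),
          sep = "=", collapse = ", ") else "defaults"
  cat("ClassifierSpec <", object@name, ">: ", p, "\n", sep = "")
})

#' Full multiclass evaluation report
#'
#' Holds the pooled confusion matrix and every derived quantity: overall
#' accuracy, per-class and macro-averaged recall/precision/F-measure
#' (percentages), and per-class and macro-averaged false-positive and
#' false-negative rates (proportions).
#'
#' @slot confusion c-by-c count matrix, rows true class, columns predicted
#' @slot accuracy overall accuracy, percent
#' @slot recall,precision,fmeasure named per-class vectors, percent
#' @slot overallRecall,overallPrecision,overallFmeasure unweighted (macro)
#'   means over classes, percent
#' @slot fpr,fnr named per-class false-positive / false-negative rates,
#'   proportions in `[0, 1]`
#' @slot overallFPR,overallFNR macro means of `fpr` / `fnr`
#' @export
setClass("MetricsReport",
         representation(confusion = "matrix", accuracy = "numeric",
                        recall = "numeric", precision = "numeric",
                        fmeasure = "numeric", overallRecall = "numeric",
                        overallPrecision = "numeric",
                        overallFmeasure = "numeric", fpr = "numeric",
                        fnr = "numeric", overallFPR = "numeric",
                        overallFNR = "numeric"))

setValidity("MetricsReport", function(object) {
  msg <- character()
  pct <- c(object@accuracy, object@recall, object@precision, object@fmeasure,
           object@overallRecall, object@overallPrecision,
           object@overallFmeasure)
  if (any(pct < -1e-9 | pct > 100 + 1e-9))
    msg <- c(msg, "percentages must lie in [0, 100]")
  if (any(c(object@fpr, object@fnr) < -1e-9 |
          c(object@fpr, object@fnr) > 1 + 1e-9))
    msg <- c(msg, "FPR/FNR must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport (", nrow(object@confusion), " classes, ",
      sum(object@confusion), " samples)\n", sep = "")
  cat(sprintf("  accuracy %.2f%% | macro recall %.2f%% | macro precision %.2f%% | macro F %.2f%%\n",
              object@accuracy, object@overallRecall, object@overallPrecision,
              object@overallFmeasure))
  cat(sprintf("  macro FPR %.4f | macro FNR %.4f\n",
              object@overallFPR, object@overallFNR))
})
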