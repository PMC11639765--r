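#' @importFrom class knn
#' @importFrom e1071 naiveBayes svm
#' @importFrom rpart rpart
#' @importFrom randomForest randomForest
NULL

# Train on (xTrain, yTrain) and predict labels for xTest.  x matrices are
# samples x features with at least one column; y is a factor.  Column names
# are sanitised so formula interfaces accept arbitrary gene identifiers.
.trainPredict <- function(xTrain, yTrain, xTest, clf) {
  stopifnot(ncol(xTrain) >= 1L)
  cols <- paste0("V", seq_len(ncol(xTrain)))
  colnames(xTrain) <- cols
  colnames(xTest) <- cols
  pred <- switch(clf@name,
    knn = {
      k <- min(clf@params$k, nrow(xTrain))
      class::knn(train = xTrain, test = xTest, cl = yTrain, k = k)
    },
    nb = {
      fit <- e1071::naiveBayes(x = as.data.frame(xTrain), y = yTrain)
      stats::predict(fit, as.data.frame(xTest))
    },
    dt = {
      df <- data.frame(as.data.frame(xTrain), .cls = yTrain)
      fit <- rpart::rpart(.cls ~ ., data = df, method = "class")
      stats::predict(fit, as.data.frame(xTest), type = "class")
    },
    rf = {
      fit <- randomForest::randomForest(x = xTrain, y = yTrain,
                                        ntree = clf@params$ntree)
      stats::predict(fit, xTest)
    },
    svm = {
      fit <- e1071::svm(x = xTrain, y = yTrain, kernel = clf@params$kernel,
                        scale = FALSE)
      stats::predict(fit, xTest)
    })
  factor(as.character(pred), levels = levels(yTrain))
}

# Pooled out-of-fold predictions for a masked dataset.  Returns a factor of
# length n aligned with the samples.  Stochastic learners and fold
# assignment are driven by `seed`; folds are reduced (with a warning) when
# the smallest class has fewer members than requested folds.
.cvPredict <- function(dataset, mask, clf, folds, stratified, seed) {
  x <- exprsMatrix(dataset)[, mask == 1L, drop = FALSE]
  y <- droplevels(factor(classLabels(dataset),
                         levels = classNames(dataset)))
  n <- nrow(x)
  minClass <- min(table(y))
  if (stratified && folds > minClass) {
    warning(sprintf("reducing folds from %d to smallest class size %d",
                    folds, minClass))
    folds <- max(2L, minClass)
  }
  if (folds > n) {
    warning(sprintf("reducing folds from %d to n = %d", folds, n))
    folds <- n
  }
  fold <- if (stratified) .stratifiedFolds(y, folds, seed)
          else .plainFolds(n, folds, seed)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  .withSeed(seed + 1L, {
    for (f in sort(unique(fold))) {
      test <- fold == f
      pred[test] <- .trainPredict(x[!test, , drop = FALSE], y[!test],
                                  x[test, , drop = FALSE], clf)
    }
  })
  list(truth = y, pred = pred, folds = folds)
}

#' Misclassification-rate fitness of a feature mask
#'
#' The DE objective: stratified k-fold cross-validation of the chosen
#' classifier on the masked dataset, returning the pooled fraction of
#' incorrectly classified samples (1 minus the classification rate).  The
#' empty mask returns the worst fitness 1.0 as a sentinel without training
#' anything.  The result is deterministic given the fitness seed and the
#' classifier seed; fold assignment depends only on `seed`, so the same
#' mask always receives the same value within a run.
#'
#' @param dataset an [ExpressionDataset-class]
#' @param mask 0/1 mask over the features
#' @param classifier a [ClassifierSpec-class] (default kNN, k = 3)
#' @param folds inner CV folds (default 5)
#' @param stratified preserve class proportions per fold (default TRUE)
#' @param seed fold-assignment / learner seed
#' @return misclassification rate in `[0, 1]`
#' @export
misclassificationFitness <- function(dataset, mask,
                                     classifier = classifierSpec("knn"),
                                     folds = 5L, stratified = TRUE,
                                     seed = 1L) {
  mask <- .checkMask(mask, nFeatures(dataset))
  if (sum(mask) == 0L) return(1.0)
  cv <- .cvPredict(dataset, mask, classifier, as.integer(folds),
                   stratified, as.integer(seed))
  mean(cv$pred != cv$truth)
}

#' Memoised fitness function over a fixed dataset
#'
#' Wraps [misclassificationFitness()] into a `function(mask)` suitable for
#' [runDE()], caching results by mask so re-evaluated individuals cost
#' nothing.  Valid because the fitness is deterministic given the seed.
#'
#' @inheritParams misclassificationFitness
#' @return function taking a 0/1 mask and returning its fitness
#' @export
makeFitnessFunction <- function(dataset, classifier = classifierSpec("knn"),
                                folds = 5L, stratified = TRUE, seed = 1L) {
  cache <- new.env(parent = emptyenv())
  force(dataset); force(classifier)
  function(mask) {
    key <- paste(mask, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- misclassificationFitness(dataset, mask, classifier, folds,
                                    stratified, seed)
    cache[[key]] <- val
    val
  }
}
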