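#' Confusion matrix of true against predicted labels
#'
#' @param yTrue,yPred equal-length label vectors; predictions must be drawn
#'   from `classNames`
#' @param classNames ordered class names; defaults to the unique true
#'   labels in first-appearance order
#' @return c-by-c integer matrix, `counts[i, j]` = number of samples of
#'   true class i predicted as class j
#' @examples
#' confusionMatrix(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
#' @export
confusionMatrix <- function(yTrue, yPred, classNames = NULL) {
  yTrue <- as.character(yTrue)
  yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred))
    stop("label vectors have different lengths")
  if (is.null(classNames)) classNames <- unique(yTrue)
  if (!all(yPred %in% classNames))
    stop("predicted label(s) outside classNames: ",
         paste(setdiff(unique(yPred), classNames), collapse = ", "))
  if (!all(yTrue %in% classNames))
    stop("true label(s) outside classNames")
  tab <- table(factor(yTrue, levels = classNames),
               factor(yPred, levels = classNames))
  m <- matrix(as.integer(tab), nrow = length(classNames),
              dimnames = list(true = classNames, predicted = classNames))
  m
}

# One-vs-rest counts per class from a confusion matrix.
.ovrCounts <- function(cm) {
  tot <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- tot - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

.safeRatio <- function(num, den, what) {
  out <- ifelse(den == 0, 0, num / den)
  if (any(den == 0))
    warning(sprintf("zero denominator in %s for class(es) %s; reporting 0",
                    what,
                    paste(rownames(as.matrix(num))[den == 0], collapse = ", ")),
            call. = FALSE)
  out
}

#' Binary classification metrics for a designated positive class
#'
#' Accuracy, recall, precision and F-measure as percentages, plus the
#' false-positive and false-negative rates as proportions, all computed
#' from the one-vs-rest counts of the positive class.  Zero denominators
#' (no true positives predicted or present) yield 0 with a warning.
#'
#' @param cm 2-by-2 confusion matrix from [confusionMatrix()]
#' @param positive name of the positive class (default first row)
#' @return named list: `accuracy`, `recall`, `precision`, `fmeasure`
#'   (percent), `fpr`, `fnr` (proportions)
#' @export
binaryMetrics <- function(cm, positive = rownames(cm)[1]) {
  if (nrow(cm) != 2L) stop("binaryMetrics requires a 2-class matrix")
  i <- match(positive, rownames(cm))
  if (is.na(i)) stop("unknown positive class: ", positive)
  cnt <- .ovrCounts(cm)
  tp <- cnt$tp[i]; fp <- cnt$fp[i]; fn <- cnt$fn[i]; tn <- cnt$tn[i]
  recall <- .safeRatio(tp, tp + fn, "recall") * 100
  precision <- .safeRatio(tp, tp + fp, "precision") * 100
  fmeas <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(accuracy = unname((tp + tn) / sum(cm) * 100),
       recall = unname(recall), precision = unname(precision),
       fmeasure = unname(fmeas),
       fpr = unname(.safeRatio(fp, fp + tn, "FPR")),
       fnr = unname(.safeRatio(fn, fn + tp, "FNR")))
}

#' Per-class and overall error rates
#'
#' One-vs-rest false-positive rate `FP_i / (FP_i + TN_i)` and
#' false-negative rate `FN_i / (FN_i + TP_i)` per class, with unweighted
#' (macro) means as the overall values.  Zero denominators yield 0 with a
#' warning.
#'
#' @param cm confusion matrix from [confusionMatrix()]
#' @return list: `fpr`, `fnr` (named per-class vectors), `overallFPR`,
#'   `overallFNR`
#' @export
errorRates <- function(cm) {
  cnt <- .ovrCounts(cm)
  fpr <- .safeRatio(cnt$fp, cnt$fp + cnt$tn, "FPR")
  fnr <- .safeRatio(cnt$fn, cnt$fn + cnt$tp, "FNR")
  list(fpr = fpr, fnr = fnr,
       overallFPR = mean(fpr), overallFNR = mean(fnr))
}

#' Macro-averaged multiclass metrics
#'
#' Builds the full [MetricsReport-class] from a confusion matrix: overall
#' accuracy, per-class one-vs-rest recall/precision/F-measure with their
#' unweighted (macro) means as the overall values, and per-class and macro
#' FPR/FNR.  Per-class F falls back to 0 when precision + recall is 0.
#'
#' @param cm confusion matrix from [confusionMatrix()]
#' @return a [MetricsReport-class]
#' @export
multiclassMetrics <- function(cm) {
  cnt <- .ovrCounts(cm)
  recall <- .safeRatio(cnt$tp, cnt$tp + cnt$fn, "recall") * 100
  precision <- .safeRatio(cnt$tp, cnt$tp + cnt$fp, "precision") * 100
  fmeas <- ifelse(precision + recall == 0, 0,
                  2 * precision * recall / (precision + recall))
  er <- errorRates(cm)
  new("MetricsReport", confusion = cm,
      accuracy = sum(diag(cm)) / sum(cm) * 100,
      recall = recall, precision = precision, fmeasure = fmeas,
      overallRecall = mean(recall), overallPrecision = mean(precision),
      overallFmeasure = mean(fmeas),
      fpr = er$fpr, fnr = er$fnr,
      overallFPR = er$overallFPR, overallFNR = er$overallFNR)
}

#' Cross-validated evaluation of a feature mask
#'
#' Stratified k-fold cross-validation (10 folds by default, the protocol
#' used for final evaluation) of a classifier on the masked dataset.
#' Out-of-fold predictions are pooled into a single confusion matrix from
#' which every metric is derived.  Folds are reduced with a warning when
#' the smallest class is smaller than the requested fold count.
#'
#' @inheritParams misclassificationFitness
#' @param folds evaluation folds (default 10)
#' @return list with `report` (a [MetricsReport-class]), `confusion`, the
#'   pooled `predictions` factor and the fold count actually `foldsUsed`
#' @export
crossValidate <- function(dataset, mask, classifier = classifierSpec("knn"),
                          folds = 10L, stratified = TRUE, seed = 1L) {
  mask <- .checkMask(mask, nFeatures(dataset))
  if (sum(mask) == 0L) stop("mask selects no features")
  cv <- .cvPredict(dataset, mask, classifier, as.integer(folds),
                   stratified, as.integer(seed))
  cm <- confusionMatrix(cv$truth, cv$pred, classNames = levels(cv$truth))
  list(report = multiclassMetrics(cm), confusion = cm,
       predictions = cv$pred, foldsUsed = cv$folds)
}
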