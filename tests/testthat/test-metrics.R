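test_that("confusion matrix tallies true-by-predicted counts", {
  cm <- confusionMatrix(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(unname(cm), matrix(c(1L, 0L, 1L, 2L), nrow = 2))
  cmDiag <- confusionMatrix(c("x", "y", "z"), c("x", "y", "z"),
                            classNames = c("x", "y", "z"))
  expect_equal(unname(diag(cmDiag)), rep(1L, 3))
  expect_equal(sum(cmDiag) - sum(diag(cmDiag)), 0L)
  allPos <- confusionMatrix(c("p", "p", "n"), c("p", "p", "p"),
                            classNames = c("p", "n"))
  expect_equal(unname(colSums(allPos)), c(3L, 0L))
  expect_error(confusionMatrix(c("a", "b"), c("a", "q"),
                               classNames = c("a", "b")), "outside")
})

test_that("binary metrics reproduce the worked confusion matrix", {
  # TP=50 TN=30 FP=10 FN=10, positive class first
  cm <- matrix(c(50L, 10L, 10L, 30L), nrow = 2, byrow = TRUE,
               dimnames = list(true = c("pos", "neg"),
                               predicted = c("pos", "neg")))
  b <- binaryMetrics(cm, positive = "pos")
  expect_equal(b$accuracy, 80)
  expect_equal(b$recall, 50 / 60 * 100, tolerance = 1e-12)
  expect_equal(b$precision, 50 / 60 * 100, tolerance = 1e-12)
  expect_equal(b$fmeasure, 50 / 60 * 100, tolerance = 1e-12)
  expect_equal(b$fpr, 0.25)
  expect_equal(b$fnr, 10 / 60, tolerance = 1e-12)
  perfect <- matrix(c(5L, 0L, 0L, 5L), 2,
                    dimnames = list(c("a", "b"), c("a", "b")))
  p <- binaryMetrics(perfect)
  expect_equal(unlist(p[c("accuracy", "recall", "precision", "fmeasure")]),
               c(accuracy = 100, recall = 100, precision = 100,
                 fmeasure = 100))
  allNeg <- matrix(c(0L, 3L, 0L, 4L), 2, byrow = TRUE,
                   dimnames = list(c("pos", "neg"), c("pos", "neg")))
  expect_warning(z <- binaryMetrics(allNeg, "pos"), "zero denominator")
  expect_equal(z$recall, 0)
  expect_equal(z$precision, 0)
})

test_that("multiclass metrics macro-average the per-class values", {
  cm <- matrix(c(1L, 1L, 0L, 2L), nrow = 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("A", "B")))
  r <- multiclassMetrics(cm)
  expect_equal(unname(r@precision), c(100, 200 / 3), tolerance = 1e-9)
  expect_equal(r@overallPrecision, (100 + 200 / 3) / 2, tolerance = 1e-9)
  # per-class recalls 100% and 50% average to 75%
  cm2 <- matrix(c(4L, 0L, 2L, 2L), nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(multiclassMetrics(cm2)@overallRecall, 75)
  diag3 <- diag(3L) * 5L
  dimnames(diag3) <- list(letters[1:3], letters[1:3])
  rp <- multiclassMetrics(diag3)
  expect_equal(rp@overallRecall, 100)
  expect_equal(rp@overallPrecision, 100)
  expect_equal(rp@overallFmeasure, 100)
  expect_equal(rp@overallFPR, 0)
})

test_that("error rates satisfy the recall identity", {
  cm <- matrix(c(50L, 10L, 10L, 30L), nrow = 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  er <- errorRates(cm)
  expect_equal(unname(er$fpr["pos"]), 0.25)
  expect_equal(unname(er$fnr["pos"]), 1 / 6, tolerance = 1e-12)
  r <- multiclassMetrics(cm)
  expect_equal(unname(r@fnr), unname(1 - r@recall / 100), tolerance = 1e-12)
})

test_that("all metrics equal brute-force tallies on random predictions", {
  for (i in 1:100) {
    withr::with_seed(2000 + i, {
      n <- sample(5:200, 1)
      c_ <- sample(2:5, 1)
      classes <- paste0("k", seq_len(c_))
      yTrue <- sample(classes, n, replace = TRUE)
      yPred <- sample(classes, n, replace = TRUE)
    })
    if (length(unique(yTrue)) < 2) next
    cm <- confusionMatrix(yTrue, yPred, classNames = classes)
    got <- suppressWarnings(multiclassMetrics(cm))
    want <- oracleMetrics(yTrue, yPred, classes)
    expect_equal(got@accuracy, want$accuracy, tolerance = 1e-9)
    expect_equal(unname(got@recall), want$recall, tolerance = 1e-9)
    expect_equal(unname(got@precision), want$precision, tolerance = 1e-9)
    expect_equal(unname(got@fmeasure), want$fmeasure, tolerance = 1e-9)
    expect_equal(unname(got@fpr), want$fpr, tolerance = 1e-9)
    expect_equal(unname(got@fnr), want$fnr, tolerance = 1e-9)
    expect_equal(got@overallRecall, want$overallRecall, tolerance = 1e-9)
    expect_equal(got@overallPrecision, want$overallPrecision,
                 tolerance = 1e-9)
    expect_equal(got@overallFmeasure, want$overallFmeasure,
                 tolerance = 1e-9)
    expect_equal(got@overallFPR, want$overallFPR, tolerance = 1e-9)
    expect_equal(got@overallFNR, want$overallFNR, tolerance = 1e-9)
    # overall values bracketed by the per-class extremes
    expect_gte(got@overallRecall, min(got@recall) - 1e-9)
    expect_lte(got@overallRecall, max(got@recall) + 1e-9)
  }
})

test_that("binary and multiclass agree on the positive class at c = 2", {
  for (i in 1:20) {
    withr::with_seed(300 + i, {
      yTrue <- sample(c("pos", "neg"), 40, replace = TRUE)
      yPred <- sample(c("pos", "neg"), 40, replace = TRUE)
    })
    cm <- confusionMatrix(yTrue, yPred, classNames = c("pos", "neg"))
    b <- suppressWarnings(binaryMetrics(cm, positive = "pos"))
    m <- suppressWarnings(multiclassMetrics(cm))
    expect_equal(b$accuracy, m@accuracy, tolerance = 1e-12)
    expect_equal(b$recall, unname(m@recall["pos"]), tolerance = 1e-12)
    expect_equal(b$precision, unname(m@precision["pos"]),
                 tolerance = 1e-12)
    expect_equal(b$fmeasure, unname(m@fmeasure["pos"]), tolerance = 1e-12)
    expect_equal(b$fpr, unname(m@fpr["pos"]), tolerance = 1e-12)
    expect_equal(b$fnr, unname(m@fnr["pos"]), tolerance = 1e-12)
  }
})

test_that("cross-validation pools out-of-fold predictions deterministically", {
  g <- generateDataset(syntheticSpec(samplesPerClass = c(15L, 15L),
                                     features = 30L, informative = 5L,
                                     redundant = 5L, effectSize = 3,
                                     seed = 6))
  mask <- g$truth$informativeMask
  cv1 <- crossValidate(g$dataset, mask, classifierSpec("knn", k = 1),
                       folds = 10, seed = 4)
  cv2 <- crossValidate(g$dataset, mask, classifierSpec("knn", k = 1),
                       folds = 10, seed = 4)
  expect_identical(cv1$report@accuracy, cv2$report@accuracy)
  expect_identical(cv1$confusion, cv2$confusion)
  expect_equal(sum(cv1$confusion), 30)
  # strongly separated planted features classify perfectly
  expect_equal(cv1$report@accuracy, 100)
})
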