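test_that("class entropy matches closed forms", {
  expect_equal(classEntropy(c(8, 0)), 0)
  expect_equal(classEntropy(c(4, 4)), 1)
  expect_equal(classEntropy(c(4, 4, 4, 4)), 2)
  expect_error(classEntropy(c(0, 0)), "zero")
})

test_that("information gain reproduces the hand-derived 8-sample value", {
  d <- eightSampleDataset()
  ig <- featureScores(scoreInformationGain(d))
  expect_equal(unname(ig["split"]), 1 - 0.811278, tolerance = 1e-5)
  expect_equal(unname(ig["junk"]), 0)
  # label-copy feature attains IG = H(S)
  d2 <- ExpressionDataset(cbind(copy = c(0, 0, 1, 1), x = rnorm(4)),
                          c("a", "a", "b", "b"))
  expect_equal(unname(featureScores(scoreInformationGain(d2))["copy"]), 1)
})

test_that("gain ratio is guarded and bounded", {
  d <- eightSampleDataset()
  igr <- featureScores(scoreGainRatio(d))
  # split sizes 4/4 give split information 1, so IGR = IG
  expect_equal(unname(igr["split"]), 1 - 0.811278, tolerance = 1e-5)
  expect_equal(unname(igr["junk"]), 0)   # constant feature: guarded 0
  d2 <- ExpressionDataset(cbind(copy = c(0, 0, 1, 1), x = rnorm(4)),
                          c("a", "a", "b", "b"))
  expect_equal(unname(featureScores(scoreGainRatio(d2))["copy"]), 1)
})

test_that("chi-squared reproduces contingency arithmetic", {
  # ((30,10),(10,30)) table: all E = 20, chi2 = 4 * 100/20 = 20
  labels <- rep(c("a", "b"), each = 40)
  feat <- c(rep(0, 30), rep(1, 10), rep(0, 10), rep(1, 30))
  d <- ExpressionDataset(cbind(f = feat, const = rep(2, 80)), labels)
  s <- featureScores(scoreChiSquared(d))
  expect_equal(unname(s["f"]), 20)
  expect_equal(unname(s["const"]), 0)
  # perfect association on n = 20 balanced samples gives chi2 = n
  lab2 <- rep(c("a", "b"), each = 10)
  d2 <- ExpressionDataset(cbind(f = rep(c(0, 1), each = 10)), lab2)
  expect_equal(unname(featureScores(scoreChiSquared(d2))["f"]), 20)
  # independent cross-check against the standard uncorrected statistic
  expect_equal(unname(s["f"]),
               unname(suppressWarnings(
                 stats::chisq.test(table(feat, labels),
                                   correct = FALSE))$statistic))
})

test_that("Gini gain matches closed forms", {
  lab <- c(rep("a", 4), rep("b", 4))
  d <- ExpressionDataset(cbind(copy = c(rep(0, 4), rep(1, 4)),
                               const = rep(1, 8)), lab)
  s <- featureScores(scoreGini(d))
  expect_equal(unname(s["copy"]), 0.5)   # Gini(S) = 0.5, children pure
  expect_equal(unname(s["const"]), 0)
  lab3 <- rep(c("a", "b", "c"), each = 3)
  d3 <- ExpressionDataset(cbind(x = rep(1, 9), y = rnorm(9)), lab3)
  # balanced 3-class impurity is 2/3; a constant feature gains none of it
  expect_equal(unname(featureScores(scoreGini(d3))["x"]), 0)
})

test_that("correlation scores are absolute and guarded", {
  lab <- c("a", "a", "b", "b")
  d <- ExpressionDataset(cbind(same = c(0, 0, 1, 1), neg = c(1, 1, 0, 0),
                               const = rep(3, 4)), lab)
  s <- featureScores(scoreCorrelation(d))
  expect_equal(unname(s["same"]), 1)
  expect_equal(unname(s["neg"]), 1)
  expect_equal(unname(s["const"]), 0)
})

test_that("CFS merit follows its closed form", {
  lab <- c("a", "a", "b", "b")
  d <- ExpressionDataset(cbind(f1 = c(0, 0, 1, 1), f2 = c(0, 0, 1, 1),
                               f3 = rep(1, 4)), lab)
  expect_equal(cfsMerit(d, c(1, 0, 0)), 1)            # f=1, rca=1
  expect_equal(cfsMerit(d, c(1, 1, 0)), 2 / sqrt(4))  # rca=raa=1
  expect_equal(cfsMerit(d, c(0, 0, 1)), 0)            # rca=0
  expect_error(cfsMerit(d, c(0, 0, 0)), "empty")
})

test_that("Relief signs discriminative and anti-discriminative layouts", {
  x <- matrix(c(0, 0.1, 1.0, 1.1), ncol = 1)
  dGood <- ExpressionDataset(x, c("A", "A", "B", "B"))
  dBad <- ExpressionDataset(x, c("A", "B", "A", "B"))
  expect_gt(featureScores(scoreRelief(dGood))[1], 0)
  expect_lt(featureScores(scoreRelief(dBad))[1], 0)
  expect_equal(unname(featureScores(
    scoreRelief(dGood, sign = "literal_paper"))[1]),
    -unname(featureScores(scoreRelief(dGood))[1]))
  # constant feature scores exactly 0
  d2 <- ExpressionDataset(cbind(x, const = rep(5, 4)), c("A", "A", "B", "B"))
  expect_equal(unname(featureScores(scoreRelief(d2))["const"]), 0)
  expect_error(scoreRelief(ExpressionDataset(x, c("A", "A", "A", "B"))),
               "fewer than k\\+1")
})

test_that("Relief equals its exhaustive enumeration oracle", {
  for (seed in 1:25) {
    d <- randomTinyDataset(seed)
    lab <- as.character(classLabels(d))
    if (min(table(lab)) < 2) next
    got <- unname(featureScores(scoreRelief(d)))
    want <- unname(oracleRelief(exprsMatrix(d), lab))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("Relief subsampling is seeded and within bounds", {
  d <- randomTinyDataset(4)
  if (min(table(classLabels(d))) >= 2) {
    a <- featureScores(scoreRelief(d, sampleCount = 3, seed = 7))
    b <- featureScores(scoreRelief(d, sampleCount = 3, seed = 7))
    expect_identical(a, b)
  }
  expect_error(scoreRelief(d, sampleCount = 0), "sampleCount")
})

test_that("entropy/contingency scorers are permutation and relabel invariant", {
  d <- randomTinyDataset(11)
  n <- nSamples(d)
  perm <- withr::with_seed(1, sample.int(n))
  x <- exprsMatrix(d)
  lab <- as.character(classLabels(d))
  relab <- paste0("X", lab)
  dPerm <- ExpressionDataset(x[perm, , drop = FALSE], lab[perm])
  dRelab <- ExpressionDataset(x, relab)
  for (f in list(scoreInformationGain, scoreGainRatio, scoreChiSquared,
                 scoreGini)) {
    base <- featureScores(f(d))
    expect_equal(unname(featureScores(f(dPerm))), unname(base),
                 tolerance = 1e-12)
    expect_equal(unname(featureScores(f(dRelab))), unname(base),
                 tolerance = 1e-12)
  }
})

test_that("scorers respect their analytic bounds on random data", {
  for (seed in 101:115) {
    d <- randomTinyDataset(seed)
    hS <- classEntropy(table(classLabels(d)))
    ig <- featureScores(scoreInformationGain(d, bins = 4))
    igr <- featureScores(scoreGainRatio(d, bins = 4))
    chi <- featureScores(scoreChiSquared(d, bins = 4))
    gg <- featureScores(scoreGini(d, bins = 4))
    cr <- featureScores(scoreCorrelation(d))
    expect_true(all(ig >= -1e-12 & ig <= hS + 1e-12))
    expect_true(all(igr >= -1e-12 & igr <= 1 + 1e-12))
    expect_true(all(chi >= -1e-12))
    expect_true(all(gg >= -1e-12 & gg <= 1 - 1 / nClasses(d) + 1e-12))
    expect_true(all(cr >= 0 & cr <= 1 + 1e-12))
  }
})

test_that("a binary label-copy feature attains the maximal score", {
  withr::with_seed(5, {
    lab <- rep(c("a", "b"), each = 6)
    noise <- matrix(rnorm(12 * 4), nrow = 12,
                    dimnames = list(NULL, paste0("n", 1:4)))
    d <- ExpressionDataset(cbind(copy = as.numeric(lab == "b"), noise),
                           lab)
  })
  for (method in c("ig", "igr", "chsqr", "gind", "cr", "relief")) {
    s <- featureScores(scoreFeatures(d, method = method))
    expect_equal(unname(which.max(s)), 1L, info = method)
  }
})

test_that("ranking is a stable descending sort with index tie-breaks", {
  r <- rankFeatures(FeatureScores("ig", c(0.1, 0.9, 0.5)))
  expect_equal(rankOrder(r), c(2L, 3L, 1L))
  rTies <- rankFeatures(FeatureScores("ig", rep(0.3, 5)))
  expect_equal(rankOrder(rTies), 1:5)
  rLast <- rankFeatures(FeatureScores("ig", c(0.2, 0.2, 0.9)))
  expect_equal(rankOrder(rLast)[1], 3L)
})

test_that("top-fraction count uses round-half-up with a floor of one", {
  expect_equal(topFractionCount(100), 5L)
  expect_equal(topFractionCount(1), 1L)
  expect_equal(topFractionCount(3, 0.05), 1L)
  expect_equal(topFractionCount(10, 0.25), 3L)   # 2.5 rounds up
  expect_error(topFractionCount(10, 0), "fraction")
})

test_that("reduceDataset keeps the highest-scored features", {
  withr::with_seed(9, {
    x <- matrix(rnorm(8 * 40), nrow = 8)
    x[, 7] <- rep(c(0, 5), each = 4)
    x[, 31] <- rep(c(5, 0), each = 4)
    d <- ExpressionDataset(x, rep(c("a", "b"), each = 4))
  })
  r <- rankFeatures(scoreCorrelation(d))
  red <- reduceDataset(d, r, 0.05)
  expect_equal(sum(red$mask), 2L)
  expect_setequal(which(red$mask == 1L), c(7L, 31L))
  expect_equal(nFeatures(red$dataset), 2L)
})
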