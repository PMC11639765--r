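#' Shannon entropy of class counts
#'
#' `H = -sum p_j log2 p_j` with the `0 * log 0 = 0` convention; the result
#' lies in `[0, log2 c]` bits.
#'
#' @param counts non-negative per-class counts, total > 0
#' @return entropy in bits
#' @examples
#' classEntropy(c(4, 4))      # 1
#' classEntropy(c(8, 0))      # 0
#' @export
classEntropy <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot == 0) stop("all counts are zero")
  p <- counts[counts > 0] / tot
  -sum(p * log2(p))
}

# Gini impurity of class counts: 1 - sum p_j^2.
.giniImpurity <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(0)
  p <- counts / tot
  1 - sum(p^2)
}

#' Discretize a numeric vector into bins
#'
#' Equal-width bins span the observed range; equal-frequency bins use
#' quantile cut points (duplicate quantiles are collapsed).  A constant
#' vector maps to a single bin under either strategy.
#'
#' @param x numeric vector
#' @param bins number of bins r (>= 2)
#' @param strategy `equal_width` (default) or `equal_frequency`
#' @return integer bin index per value, in `1..r`
#' @export
discretizeFeature <- function(x, bins = 10L,
                              strategy = c("equal_width",
                                           "equal_frequency")) {
  strategy <- match.arg(strategy)
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be >= 2")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1L, length(x)))
  breaks <- if (strategy == "equal_width") {
    seq(rng[1], rng[2], length.out = bins + 1L)
  } else {
    unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                           names = FALSE, type = 7))
  }
  if (length(breaks) < 3L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = breaks, include.lowest = TRUE, labels = FALSE))
}

# Shared driver: apply a per-feature function of (bin vector, labels).
.scorePerFeature <- function(dataset, fun, bins, strategy) {
  x <- exprsMatrix(dataset)
  lab <- classLabels(dataset)
  vapply(seq_len(ncol(x)), function(j) {
    fun(discretizeFeature(x[, j], bins = bins, strategy = strategy), lab)
  }, numeric(1))
}

.igFromBins <- function(bin, lab) {
  h <- classEntropy(table(lab))
  tab <- table(bin, lab)
  w <- rowSums(tab) / sum(tab)
  h - sum(w * apply(tab, 1, classEntropy))
}

#' Information-gain filter scores
#'
#' Per feature, the reduction in class entropy achieved by partitioning the
#' samples on the discretized feature values:
#' `IG = H(S) - sum_v |S_v|/|S| H(S_v)`.  Scores lie in `[0, H(S)]`; a
#' constant feature scores 0 and a feature reproducing the label scores
#' `H(S)`.
#'
#' @param dataset an [ExpressionDataset-class]
#' @param bins,strategy discretization (see [discretizeFeature()])
#' @return a [FeatureScores-class]
#' @export
scoreInformationGain <- function(dataset, bins = 10L,
                                 strategy = "equal_width") {
  s <- .scorePerFeature(dataset, .igFromBins, bins, strategy)
  FeatureScores("ig", s, featureIds(dataset))
}

#' Gain-ratio filter scores
#'
#' Information gain divided by the split information (the entropy of the
#' bin-occupancy distribution), penalising features fragmented over many
#' bins.  A feature with zero split information (a single bin) scores 0.
#'
#' @inheritParams scoreInformationGain
#' @return a [FeatureScores-class] with scores in `[0, 1]`
#' @export
scoreGainRatio <- function(dataset, bins = 10L, strategy = "equal_width") {
  s <- .scorePerFeature(dataset, function(bin, lab) {
    split <- classEntropy(table(bin))
    if (split == 0) return(0)
    .igFromBins(bin, lab) / split
  }, bins, strategy)
  FeatureScores("igr", s, featureIds(dataset))
}

#' Chi-squared filter scores
#'
#' Per feature, the chi-squared statistic of the r-by-c contingency table of
#' discretized value against class, `sum (O - E)^2 / E` with
#' `E_ij = rowTotal_i * colTotal_j / n`.  Cells in empty rows (expected
#' count 0) contribute nothing.
#'
#' @inheritParams scoreInformationGain
#' @return a [FeatureScores-class] with non-negative scores
#' @export
scoreChiSquared <- function(dataset, bins = 10L, strategy = "equal_width") {
  s <- .scorePerFeature(dataset, function(bin, lab) {
    o <- table(bin, lab)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    ok <- e > 0
    sum((o[ok] - e[ok])^2 / e[ok])
  }, bins, strategy)
  FeatureScores("chsqr", s, featureIds(dataset))
}

#' Gini-gain filter scores
#'
#' Per feature, the decrease in Gini impurity `1 - sum_j p_j^2` achieved by
#' partitioning on the discretized values, the impurity analogue of
#' information gain.
#'
#' @inheritParams scoreInformationGain
#' @return a [FeatureScores-class] with scores in `[0, Gini(S)]`
#' @export
scoreGini <- function(dataset, bins = 10L, strategy = "equal_width") {
  s <- .scorePerFeature(dataset, function(bin, lab) {
    tab <- table(bin, lab)
    w <- rowSums(tab) / sum(tab)
    .giniImpurity(table(lab)) - sum(w * apply(tab, 1, .giniImpurity))
  }, bins, strategy)
  FeatureScores("gind", s, featureIds(dataset))
}

#' Correlation filter scores
#'
#' Absolute Pearson correlation between each feature and the
#' integer-encoded class labels.  Constant features score 0.
#'
#' @param dataset an [ExpressionDataset-class]
#' @return a [FeatureScores-class] with scores in `[0, 1]`
#' @export
scoreCorrelation <- function(dataset) {
  x <- exprsMatrix(dataset)
  codes <- encodeLabels(classLabels(dataset))$codes
  s <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (stats::sd(v) == 0) return(0)
    abs(stats::cor(v, codes))
  }, numeric(1))
  FeatureScores("cr", s, featureIds(dataset))
}

#' Correlation-based subset merit
#'
#' Merit of a feature subset: `f * rca / sqrt(f + f (f - 1) raa)` where
#' `rca` is the mean absolute feature-class Pearson correlation, `raa` the
#' mean absolute pairwise feature-feature correlation over the subset
#' (defined as 0 for a single feature), and `f` the subset size.  Rewards
#' subsets correlated with the class but mutually decorrelated.
#'
#' @param dataset an [ExpressionDataset-class]
#' @param mask 0/1 subset mask over the features (non-empty)
#' @return the scalar merit
#' @export
cfsMerit <- function(dataset, mask) {
  mask <- .checkMask(mask, nFeatures(dataset))
  f <- sum(mask)
  if (f == 0L) stop("subset is empty")
  x <- exprsMatrix(dataset)[, mask == 1L, drop = FALSE]
  codes <- encodeLabels(classLabels(dataset))$codes
  absCor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else abs(stats::cor(a, b))
  }
  rca <- mean(vapply(seq_len(f), function(j) absCor(x[, j], codes),
                     numeric(1)))
  raa <- if (f > 1L) {
    pairs <- utils::combn(f, 2)
    mean(vapply(seq_len(ncol(pairs)), function(p)
      absCor(x[, pairs[1, p]], x[, pairs[2, p]]), numeric(1)))
  } else 0
  f * rca / sqrt(f + f * (f - 1) * raa)
}

#' Relief filter scores
#'
#' Nearest-neighbour feature weighting.  For each of `sampleCount` sampled
#' instances the k nearest hits (same class) and k nearest misses (any
#' other class) are found in the full feature space under range-scaled
#' Manhattan distance, and every feature is credited with the per-feature
#' miss-distance minus hit-distance (averaged over the k neighbours); the
#' accumulated sum carries a factor 1/2.  Under the default `standard` sign
#' convention larger scores mark features that separate the classes;
#' `literal_paper` flips the sign (hit minus miss).
#'
#' @param dataset an [ExpressionDataset-class]; every class needs at least
#'   `k + 1` samples
#' @param k number of nearest hits/misses per instance (default 1)
#' @param sampleCount number of instances sampled without replacement;
#'   default all n (deterministic regardless of seed)
#' @param sign `standard` or `literal_paper`
#' @param seed seed for the instance subsample (only used when
#'   `sampleCount < n`)
#' @return a [FeatureScores-class]
#' @export
scoreRelief <- function(dataset, k = 1L, sampleCount = NULL,
                        sign = c("standard", "literal_paper"), seed = 1L) {
  sign <- match.arg(sign)
  x <- exprsMatrix(dataset)
  lab <- as.character(classLabels(dataset))
  n <- nrow(x); m <- ncol(x)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  small <- names(which(table(lab) < k + 1L))
  if (length(small))
    stop("class(es) with fewer than k+1 samples: ",
         paste(small, collapse = ", "))
  if (is.null(sampleCount)) sampleCount <- n
  if (sampleCount < 1L || sampleCount > n)
    stop("sampleCount must lie in [1, n]")
  # range scaling: per-feature distances in [0, 1]; constant features
  # contribute zero distance everywhere and end with score 0
  rng <- apply(x, 2, function(v) diff(range(v)))
  scale <- ifelse(rng == 0, 1, rng)
  xs <- sweep(sweep(x, 2, apply(x, 2, min)), 2, scale, "/")
  picks <- if (sampleCount < n) {
    .withSeed(seed, sample.int(n, sampleCount))
  } else seq_len(n)
  w <- numeric(m)
  for (b in picks) {
    d <- abs(sweep(xs, 2, xs[b, ], "-"))      # n x m per-feature distances
    tot <- rowSums(d)
    hits <- setdiff(which(lab == lab[b]), b)
    misses <- which(lab != lab[b])
    nearest <- function(idx) idx[order(tot[idx], idx)][seq_len(k)]
    hb <- nearest(hits)
    mb <- nearest(misses)
    contrib <- colMeans(d[mb, , drop = FALSE]) -
      colMeans(d[hb, , drop = FALSE])
    w <- w + if (sign == "standard") contrib else -contrib
  }
  FeatureScores("relief", w / 2, featureIds(dataset))
}

#' Score features with a named filter method
#'
#' Dispatcher over the six filters: `ig`, `igr`, `chsqr`, `gind`, `cr`,
#' `relief`.
#'
#' @param dataset an [ExpressionDataset-class]
#' @param method filter name
#' @param bins,strategy discretization for the entropy/contingency filters
#' @param reliefK,reliefSampleCount,reliefSign,seed Relief options
#' @return a [FeatureScores-class]
#' @export
scoreFeatures <- function(dataset,
                          method = c("ig", "igr", "chsqr", "cr", "gind",
                                     "relief"),
                          bins = 10L, strategy = "equal_width",
                          reliefK = 1L, reliefSampleCount = NULL,
                          reliefSign = "standard", seed = 1L) {
  method <- match.arg(method)
  switch(method,
         ig = scoreInformationGain(dataset, bins, strategy),
         igr = scoreGainRatio(dataset, bins, strategy),
         chsqr = scoreChiSquared(dataset, bins, strategy),
         gind = scoreGini(dataset, bins, strategy),
         cr = scoreCorrelation(dataset),
         relief = scoreRelief(dataset, k = reliefK,
                              sampleCount = reliefSampleCount,
                              sign = reliefSign, seed = seed))
}

#' Rank features by score
#'
#' Stable descending sort; ties are broken by ascending feature index so
#' rankings are reproducible across platforms.
#'
#' @param scores a [FeatureScores-class]
#' @return a [FeatureRanking-class]
#' @export
rankFeatures <- function(scores) {
  ord <- order(-scores@scores, seq_along(scores@scores))
  new("FeatureRanking", order = as.integer(ord), scores = scores)
}

#' Number of features retained by a top-fraction cut
#'
#' Round-half-up of `fraction * m`, floored at one feature.  With the
#' default 5 percent this reproduces the reduced dimensionalities of the
#' four benchmark microarray datasets: 5,597 -> 280, 6,129 -> 306,
#' 12,600 -> 630, 24,481 -> 1,224.
#'
#' @param m total feature count
#' @param fraction fraction to keep, in `(0, 1]` (default 0.05)
#' @return the retained count
#' @examples
#' topFractionCount(5597)   # 280
#' @export
topFractionCount <- function(m, fraction = 0.05) {
  if (m < 1L) stop("m must be >= 1")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  max(1L, as.integer(floor(fraction * m + 0.5)))
}

#' Reduce a dataset to its top-ranked features
#'
#' Keeps the [topFractionCount()] best-ranked features (original column
#' order preserved) and returns both the reduced dataset and the 0/1 mask
#' over the original features.
#'
#' @param dataset an [ExpressionDataset-class]
#' @param ranking a [FeatureRanking-class] built on this dataset
#' @param fraction fraction to keep (default 0.05)
#' @return list with `dataset` (reduced) and `mask` (length-m 0/1 vector)
#' @export
reduceDataset <- function(dataset, ranking, fraction = 0.05) {
  m <- nFeatures(dataset)
  if (length(rankOrder(ranking)) != m)
    stop("ranking was not built on this dataset")
  keep <- topFractionCount(m, fraction)
  mask <- integer(m)
  mask[rankOrder(ranking)[seq_len(keep)]] <- 1L
  list(dataset = subsetFeatures(dataset, mask), mask = mask)
}
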