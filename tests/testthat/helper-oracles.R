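# Brute-force oracles, written independently of the package internals:
# explicit loops over partitions and label vectors, no shared code paths
# beyond the discretizer primitive they are defined on.

# Random small dataset for oracle comparisons.
randomTinyDataset <- function(seed, nMax = 12L, mMax = 6L, cMax = 3L) {
  withr::with_seed(seed, {
    n <- sample(4:nMax, 1)
    m <- sample(2:mMax, 1)
    c <- sample(2:cMax, 1)
    labels <- sample(paste0("c", seq_len(c)), n, replace = TRUE)
    while (length(unique(labels)) < 2)
      labels <- sample(paste0("c", seq_len(c)), n, replace = TRUE)
    x <- matrix(round(rnorm(n * m), 2), nrow = n)
    # occasional constant / duplicated-value columns to exercise edge cases
    if (runif(1) < 0.3) x[, 1] <- x[1, 1]
    ExpressionDataset(x, labels)
  })
}

oracleEntropy <- function(labels) {
  h <- 0
  for (cl in unique(labels)) {
    p <- sum(labels == cl) / length(labels)
    if (p > 0) h <- h - p * log2(p)
  }
  h
}

oracleGiniImp <- function(labels) {
  s <- 0
  for (cl in unique(labels)) s <- s + (sum(labels == cl) / length(labels))^2
  1 - s
}

# IG / IGR / Gini gain / chi-squared from an explicit partition by bin value
oracleIG <- function(bins, labels) {
  h <- oracleEntropy(labels)
  for (v in unique(bins)) {
    idx <- bins == v
    h <- h - sum(idx) / length(bins) * oracleEntropy(labels[idx])
  }
  h
}

oracleIGR <- function(bins, labels) {
  split <- oracleEntropy(bins)
  if (split == 0) return(0)
  oracleIG(bins, labels) / split
}

oracleGiniGain <- function(bins, labels) {
  g <- oracleGiniImp(labels)
  for (v in unique(bins)) {
    idx <- bins == v
    g <- g - sum(idx) / length(bins) * oracleGiniImp(labels[idx])
  }
  g
}

oracleChiSq <- function(bins, labels) {
  n <- length(bins)
  stat <- 0
  for (v in unique(bins)) {
    for (cl in unique(labels)) {
      o <- sum(bins == v & labels == cl)
      e <- sum(bins == v) * sum(labels == cl) / n
      if (e > 0) stat <- stat + (o - e)^2 / e
    }
  }
  stat
}

oracleAbsPCC <- function(x, codes) {
  if (length(unique(x)) == 1) return(0)
  mx <- mean(x); mc <- mean(codes)
  num <- sum((x - mx) * (codes - mc))
  den <- sqrt(sum((x - mx)^2) * sum((codes - mc)^2))
  if (den == 0) 0 else abs(num / den)
}

# Relief oracle: full enumeration of per-instance nearest hits/misses on the
# range-scaled matrix (k = 1, all instances, standard sign).
oracleRelief <- function(x, labels) {
  n <- nrow(x); m <- ncol(x)
  xs <- x
  for (j in seq_len(m)) {
    r <- max(x[, j]) - min(x[, j])
    xs[, j] <- if (r == 0) 0 else (x[, j] - min(x[, j])) / r
  }
  w <- numeric(m)
  for (b in seq_len(n)) {
    dTot <- rep(Inf, n)
    for (i in seq_len(n)) if (i != b) dTot[i] <- sum(abs(xs[i, ] - xs[b, ]))
    hitCand <- which(labels == labels[b]); hitCand <- hitCand[hitCand != b]
    missCand <- which(labels != labels[b])
    hit <- hitCand[which.min(dTot[hitCand])]
    miss <- missCand[which.min(dTot[missCand])]
    w <- w + (abs(xs[miss, ] - xs[b, ]) - abs(xs[hit, ] - xs[b, ]))
  }
  w / 2
}

# Metric oracle: explicit tallies straight from the label vectors.
oracleMetrics <- function(yTrue, yPred, classes) {
  n <- length(yTrue)
  acc <- sum(yTrue == yPred) / n * 100
  recall <- precision <- fmeas <- fpr <- fnr <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(yTrue == cl & yPred == cl)
    fp <- sum(yTrue != cl & yPred == cl)
    fn <- sum(yTrue == cl & yPred != cl)
    tn <- sum(yTrue != cl & yPred != cl)
    recall[i] <- if (tp + fn == 0) 0 else tp / (tp + fn) * 100
    precision[i] <- if (tp + fp == 0) 0 else tp / (tp + fp) * 100
    fmeas[i] <- if (precision[i] + recall[i] == 0) 0 else
      2 * precision[i] * recall[i] / (precision[i] + recall[i])
    fpr[i] <- if (fp + tn == 0) 0 else fp / (fp + tn)
    fnr[i] <- if (fn + tp == 0) 0 else fn / (fn + tp)
  }
  list(accuracy = acc, recall = recall, precision = precision,
       fmeasure = fmeas, fpr = fpr, fnr = fnr,
       overallRecall = mean(recall), overallPrecision = mean(precision),
       overallFmeasure = mean(fmeas), overallFPR = mean(fpr),
       overallFNR = mean(fnr))
}

# 1-nearest-neighbour leave-one-fold-out by hand (Euclidean), for checking
# classifier plumbing on tiny instances.
oracleNN1 <- function(xTrain, yTrain, xTest) {
  out <- character(nrow(xTest))
  for (i in seq_len(nrow(xTest))) {
    d <- apply(xTrain, 1, function(r) sqrt(sum((r - xTest[i, ])^2)))
    out[i] <- as.character(yTrain[which.min(d)])
  }
  out
}

# The worked 8-sample example: balanced binary labels, a binary feature
# splitting into (3+,1-) and (1+,3-).
eightSampleDataset <- function() {
  labels <- c("pos", "pos", "pos", "pos", "neg", "neg", "neg", "neg")
  feat <- c(0, 0, 0, 1, 0, 1, 1, 1)   # low bin: 3 pos 1 neg; high: 1 pos 3 neg
  ExpressionDataset(cbind(split = feat, junk = rep(1, 8)), labels)
}
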