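#' Specification of a synthetic expression dataset
#'
#' Describes a seeded gene-expression-like dataset with planted structure:
#' `informative` genes whose class-conditional means are spaced by
#' `effectSize * noiseSigma` across the classes, `redundant` genes built as
#' `rho * parent + sqrt(1 - rho^2) * noise` from a random informative
#' parent, and pure Gaussian noise for the rest.  The defaults emulate the
#' benchmark microarray regime (tens of samples, 2-5 classes, a small
#' informative core drowned in noise) at a scale suited to tests:
#' two classes of 30 samples, 600 genes of which 15 are informative and 30
#' redundant, effect size 1.5 and parent-child correlation 0.8.
#'
#' @param samplesPerClass positive integer per class (2 to 5 classes)
#' @param features total gene count m
#' @param informative number of informative genes q
#' @param redundant number of redundant genes
#' @param effectSize between-class mean shift in units of `noiseSigma`
#' @param redundancyRho target parent-child correlation, in `[0, 1)`
#' @param noiseSigma baseline noise standard deviation
#' @param seed RNG seed
#' @return a validated `SyntheticSpec` (classed list)
#' @seealso [generateDataset()]
#' @export
syntheticSpec <- function(samplesPerClass = c(30L, 30L), features = 600L,
                          informative = 15L, redundant = 30L,
                          effectSize = 1.5, redundancyRho = 0.8,
                          noiseSigma = 1, seed = 1L) {
  spec <- list(samplesPerClass = as.integer(samplesPerClass),
               features = as.integer(features),
               informative = as.integer(informative),
               redundant = as.integer(redundant),
               effectSize = as.numeric(effectSize),
               redundancyRho = as.numeric(redundancyRho),
               noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
  nc <- length(spec$samplesPerClass)
  if (nc < 2L || nc > 5L) stop("between 2 and 5 classes are supported")
  if (any(spec$samplesPerClass < 1L)) stop("samplesPerClass must be positive")
  if (spec$informative < 0L || spec$redundant < 0L)
    stop("feature counts must be non-negative")
  if (spec$informative + spec$redundant > spec$features)
    stop("informative + redundant must not exceed total features")
  if (spec$redundant > 0L && spec$informative == 0L)
    stop("redundant features require at least one informative parent")
  if (spec$effectSize < 0) stop("effectSize must be >= 0")
  if (spec$redundancyRho < 0 || spec$redundancyRho >= 1)
    stop("redundancyRho must lie in [0, 1)")
  if (spec$noiseSigma <= 0) stop("noiseSigma must be positive")
  structure(spec, class = "SyntheticSpec")
}

#' Generate a synthetic expression dataset with known ground truth
#'
#' Draws the dataset described by a [syntheticSpec()].  Gene positions for
#' the informative and redundant blocks are randomised; the returned truth
#' records the two masks and the parent of every redundant gene.
#' Class-conditional means of informative gene j are
#' `(k - (c + 1)/2) * effectSize * noiseSigma` for class k, i.e. classes
#' are spaced `effectSize` noise-standard-deviations apart.
#'
#' @param spec a [syntheticSpec()]
#' @return list with `dataset` (an [ExpressionDataset-class]) and `truth`
#'   (list: `informativeMask`, `redundantMask`, `parents` — named integer
#'   vector mapping redundant gene index to its parent's index)
#' @examples
#' g <- generateDataset(syntheticSpec(seed = 42))
#' table(classLabels(g$dataset))
#' @export
generateDataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  nPer <- spec$samplesPerClass
  nc <- length(nPer)
  n <- sum(nPer)
  m <- spec$features
  labels <- rep(paste0("class", seq_len(nc)), times = nPer)
  .withSeed(spec$seed, {
    x <- matrix(stats::rnorm(n * m, sd = spec$noiseSigma), nrow = n)
    pos <- sample.int(m, spec$informative + spec$redundant)
    infIdx <- pos[seq_len(spec$informative)]
    redIdx <- pos[-seq_len(spec$informative)]
    classOf <- rep(seq_len(nc), times = nPer)
    shift <- (classOf - (nc + 1) / 2) * spec$effectSize * spec$noiseSigma
    for (j in infIdx) x[, j] <- x[, j] + shift
    parents <- integer(0)
    if (length(redIdx)) {
      parents <- infIdx[((seq_along(redIdx) - 1L) %% length(infIdx)) + 1L]
      rho <- spec$redundancyRho
      for (i in seq_along(redIdx)) {
        eps <- stats::rnorm(n, sd = spec$noiseSigma)
        x[, redIdx[i]] <- rho * x[, parents[i]] + sqrt(1 - rho^2) * eps
      }
      names(parents) <- paste0("g", redIdx)
    }
  })
  infMask <- integer(m); infMask[infIdx] <- 1L
  redMask <- integer(m); redMask[redIdx] <- 1L
  ds <- ExpressionDataset(x, labels,
                          featureIds = paste0("g", seq_len(m)),
                          sampleIds = paste0("s", seq_len(n)))
  list(dataset = ds,
       truth = list(informativeMask = infMask, redundantMask = redMask,
                    parents = parents, spec = spec))
}

#' Recovery of planted features by a selection mask
#'
#' Measures how well a selected feature set recovers the planted signal of
#' a synthetic dataset.  Precision is the fraction of selected genes that
#' carry signal (informative or redundant); informative recall is the
#' fraction of informative genes whose signal was captured — either the
#' gene itself or any of its redundant children is selected.
#'
#' @param selected 0/1 mask of selected features
#' @param truth the `truth` component of [generateDataset()]
#' @return list with `precision` and `recallInformative`
#' @export
recoveryReport <- function(selected, truth) {
  m <- length(truth$informativeMask)
  selected <- .checkMask(selected, m)
  signal <- truth$informativeMask == 1L | truth$redundantMask == 1L
  nSel <- sum(selected)
  precision <- if (nSel == 0L) 0 else sum(selected == 1L & signal) / nSel
  infIdx <- which(truth$informativeMask == 1L)
  captured <- vapply(infIdx, function(j) {
    if (selected[j] == 1L) return(TRUE)
    children <- as.integer(sub("^g", "",
                               names(truth$parents)[truth$parents == j]))
    any(selected[children] == 1L)
  }, logical(1))
  list(precision = precision,
       recallInformative = if (length(infIdx)) mean(captured) else NA_real_)
}
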