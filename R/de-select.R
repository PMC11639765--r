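#' Binary difference-vector mutation
#'
#' Builds the mutant mask from three distinct population members: positions
#' where `xr1` and `xr2` agree contribute a zero difference and the mutant
#' copies `xr3`; positions where they disagree take the difference bit
#' `xr1[d]`, and a difference bit of 1 forces the mutant bit to 1.
#'
#' @param xr1,xr2,xr3 equal-length 0/1 masks
#' @return the mutant 0/1 mask
#' @examples
#' mutateBinary(c(1, 0, 1), c(1, 1, 0), c(0, 1, 0))  # c(0, 1, 1)
#' @export
mutateBinary <- function(xr1, xr2, xr3) {
  if (length(xr1) != length(xr2) || length(xr1) != length(xr3))
    stop("mask lengths differ")
  xr1 <- .checkMask(xr1); xr2 <- .checkMask(xr2); xr3 <- .checkMask(xr3)
  diffv <- ifelse(xr1 == xr2, 0L, xr1)
  ifelse(diffv == 1L, 1L, xr3)
}

#' Classical continuous DE mutation
#'
#' The real-valued reference operator `xr1 + F * (xr3 - xr2)`.  The binary
#' search does not use it; it is provided for completeness and testing.
#'
#' @param xr1,xr2,xr3 equal-length numeric vectors
#' @param f mutation factor in `[0, 1]`
#' @return the mutant vector
#' @export
mutateContinuous <- function(xr1, xr2, xr3, f = 0.5) {
  if (length(xr1) != length(xr2) || length(xr1) != length(xr3))
    stop("vector lengths differ")
  if (f < 0 || f > 1) stop("mutation factor must be in [0, 1]")
  xr1 + f * (xr3 - xr2)
}

#' Binomial crossover
#'
#' Builds the trial mask: position `d` takes the mutant bit when a fresh
#' uniform draw is `<= CR` or when `d` equals the one forced coordinate
#' `d_rand` (drawn uniformly once per trial), otherwise the source bit.
#' Draws come from the current R random stream; seed the session (or call
#' from [runDE()]) for reproducibility.
#'
#' @param source,mutant equal-length 0/1 masks
#' @param crossoverRate CR in `[0, 1]`
#' @return the trial 0/1 mask
#' @export
crossoverMask <- function(source, mutant, crossoverRate = 0.9) {
  if (length(source) != length(mutant)) stop("mask lengths differ")
  if (crossoverRate < 0 || crossoverRate > 1)
    stop("crossoverRate must be in [0, 1]")
  source <- .checkMask(source); mutant <- .checkMask(mutant)
  m <- length(source)
  dRand <- sample.int(m, 1L)
  delta <- stats::runif(m)
  ifelse(delta <= crossoverRate | seq_len(m) == dRand, mutant, source)
}

#' Greedy one-to-one selection
#'
#' The trial replaces the source only on strict fitness improvement (lower
#' misclassification rate); ties retain the source.
#'
#' @param source,trial 0/1 masks
#' @param fSource,fTrial their fitness values in `[0, 1]`
#' @return the surviving mask
#' @export
selectSurvivor <- function(source, trial, fSource, fTrial) {
  if (fTrial < fSource) trial else source
}

# Bernoulli(0.5) population; all-zero individuals are repaired by setting
# one uniformly chosen bit.  Assumes a seeded RNG context.
.initPopulation <- function(m, p) {
  pop <- lapply(seq_len(p), function(i) {
    bits <- as.integer(stats::runif(m) < 0.5)
    if (sum(bits) == 0L) bits[sample.int(m, 1L)] <- 1L
    bits
  })
  pop
}

#' Initialize a DE population
#'
#' `populationSize` masks of dimension `m` with independent Bernoulli(0.5)
#' bits from the seeded generator; an all-zero draw is repaired by setting
#' one uniformly chosen bit, so every individual selects at least one
#' feature.
#'
#' @param m mask dimension (>= 2)
#' @param config a [DEConfig-class]; its seed fixes the draw
#' @return list of `populationSize` 0/1 masks
#' @export
initializePopulation <- function(m, config = deConfig()) {
  if (m < 2L) stop("m must be >= 2")
  .withSeed(config@seed, .initPopulation(m, config@populationSize))
}

#' Run the binary differential-evolution search
#'
#' Minimises `fitnessFn` (a function of a 0/1 mask returning a value in
#' `[0, 1]`, typically a cross-validated misclassification rate) over
#' non-empty masks of dimension `m`.  Each generation every individual is
#' challenged by a trial built from three distinct random partners via
#' [mutateBinary()] and [crossoverMask()]; the trial survives only on
#' strict improvement.  All-zero trial masks are assigned fitness 1.0
#' without calling `fitnessFn`, so the search itself avoids the empty
#' subset.  The returned best is the minimum over every individual ever
#' evaluated, making the recorded trajectory non-increasing.
#'
#' @param fitnessFn function(mask) -> fitness in `[0, 1]`
#' @param m mask dimension (>= 2)
#' @param config a [DEConfig-class]
#' @return a [DEResult-class]
#' @examples
#' target <- c(1, 0, 1, 1, 0)
#' res <- runDE(function(b) mean(b != target), m = 5,
#'              config = deConfig(populationSize = 10, maxGenerations = 20,
#'                                seed = 1))
#' bestFitness(res)
#' @export
runDE <- function(fitnessFn, m, config = deConfig()) {
  if (m < 2L) stop("m must be >= 2")
  p <- config@populationSize
  cr <- config@crossoverRate
  g <- config@maxGenerations
  .withSeed(config@seed, {
    pop <- .initPopulation(m, p)
    evals <- 0L
    fit <- vapply(seq_len(p), function(i) {
      evals <<- evals + 1L
      .evalFitness(fitnessFn, pop[[i]], 0L, i)
    }, numeric(1))
    bestIdx <- which.min(fit)
    bestMask <- pop[[bestIdx]]
    bestFit <- fit[bestIdx]
    history <- bestFit
    gensRun <- 0L
    sinceImprove <- 0
    for (t in seq_len(g)) {
      # generational semantics: trials challenge the current generation and
      # winners enter the population of the next one
      newPop <- pop
      newFit <- fit
      for (i in seq_len(p)) {
        partners <- sample(setdiff(seq_len(p), i), 3L)
        mutant <- mutateBinary(pop[[partners[1]]], pop[[partners[2]]],
                               pop[[partners[3]]])
        trial <- crossoverMask(pop[[i]], mutant, cr)
        fTrial <- if (sum(trial) == 0L) 1.0 else {
          evals <- evals + 1L
          .evalFitness(fitnessFn, trial, t, i)
        }
        if (fTrial < fit[i]) {
          newPop[[i]] <- trial
          newFit[i] <- fTrial
          if (fTrial < bestFit) {
            bestFit <- fTrial
            bestMask <- trial
          }
        }
      }
      pop <- newPop
      fit <- newFit
      gensRun <- t
      improved <- bestFit < history[length(history)]
      history <- c(history, bestFit)
      sinceImprove <- if (improved) 0 else sinceImprove + 1
      if (config@earlyStop &&
          (bestFit == 0 || sinceImprove >= config@patience)) break
    }
    new("DEResult", bestMask = bestMask, bestFitness = bestFit,
        generationsRun = gensRun, history = history,
        evaluations = evals)
  })
}

.evalFitness <- function(fitnessFn, mask, gen, ind) {
  f <- tryCatch(fitnessFn(mask), error = function(e)
    stop(sprintf("fitness evaluation failed at generation %d, individual %d: %s",
                 gen, ind, conditionMessage(e)), call. = FALSE))
  if (!is.finite(f) || f < 0 || f > 1)
    stop(sprintf("fitness must lie in [0, 1]; got %s at generation %d, individual %d",
                 format(f), gen, ind))
  f
}
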