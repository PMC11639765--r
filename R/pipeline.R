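#' Configuration of the hybrid filter + DE pipeline
#'
#' Bundles every stage's settings: the filter method and retained fraction,
#' the discretization and Relief options, the DE search budget, the fitness
#' classifier and inner CV folds, the evaluation classifiers and outer CV
#' folds, and the master seed from which each stage derives its own
#' reproducible sub-seed.
#'
#' @param filter filter method (`ig`, `igr`, `chsqr`, `cr`, `gind`,
#'   `relief`)
#' @param fraction top fraction of ranked features to retain (default 0.05)
#' @param bins,strategy discretization for the entropy/contingency filters
#' @param reliefK,reliefSampleCount,reliefSign Relief options
#' @param de a [DEConfig-class]; its seed slot is overridden by the derived
#'   DE sub-seed.  `maxGenerations = 0` skips the DE stage entirely and
#'   evaluates the filter-reduced feature set
#' @param fitnessClassifier a [ClassifierSpec-class] used inside the DE
#'   fitness; defaults to the first evaluation classifier
#' @param evalClassifiers list of [ClassifierSpec-class] evaluated on the
#'   final selection (default kNN)
#' @param fitnessFolds inner CV folds of the fitness (default 5)
#' @param evalFolds outer evaluation folds (default 10)
#' @param seed master seed
#' @return a validated `PipelineConfig` (classed list)
#' @export
pipelineConfig <- function(filter = "ig", fraction = 0.05, bins = 10L,
                           strategy = "equal_width", reliefK = 1L,
                           reliefSampleCount = NULL,
                           reliefSign = "standard",
                           de = deConfig(),
                           fitnessClassifier = NULL,
                           evalClassifiers = list(classifierSpec("knn")),
                           fitnessFolds = 5L, evalFolds = 10L, seed = 1L) {
  filter <- match.arg(filter, c("ig", "igr", "chsqr", "cr", "gind",
                                "relief"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  stopifnot(is(de, "DEConfig"))
  if (!is.list(evalClassifiers) || !length(evalClassifiers) ||
      !all(vapply(evalClassifiers, is, logical(1), "ClassifierSpec")))
    stop("evalClassifiers must be a non-empty list of ClassifierSpec")
  if (is.null(fitnessClassifier)) fitnessClassifier <- evalClassifiers[[1]]
  stopifnot(is(fitnessClassifier, "ClassifierSpec"))
  structure(list(filter = filter, fraction = fraction,
                 bins = as.integer(bins), strategy = strategy,
                 reliefK = as.integer(reliefK),
                 reliefSampleCount = reliefSampleCount,
                 reliefSign = reliefSign, de = de,
                 fitnessClassifier = fitnessClassifier,
                 evalClassifiers = evalClassifiers,
                 fitnessFolds = as.integer(fitnessFolds),
                 evalFolds = as.integer(evalFolds),
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the hybrid filter + DE selection pipeline end to end
#'
#' Executes the full procedure on one dataset: score all genes with the
#' configured filter, rank them, keep the top fraction, search feature
#' subsets of the reduced matrix with binary DE minimising the
#' cross-validated misclassification rate of the fitness classifier, embed
#' the DE-selected mask back over the original genes, and evaluate every
#' configured classifier on the final selection with stratified
#' cross-validation.
#'
#' Note the evaluation re-uses the data the features were selected on, as
#' in the original protocol; accuracies are therefore optimistically
#' biased relative to an external test set.  A warning records this.
#'
#' @param dataset an [ExpressionDataset-class]
#' @param config a [pipelineConfig()]
#' @return a `RunReport` (classed list) with elements `input` (n, m, c),
#'   `scores`, `ranking`, `reducedCount`, `reduceMask`, `deResult` (NULL
#'   when DE is skipped), `finalMask` (over the original genes),
#'   `selectedCount`, `selectedFeatures`, `evaluations` (named list of
#'   [crossValidate()] results, one per classifier), `seeds`, `config`
#' @export
runHybrid <- function(dataset, config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  seeds <- list(filter = .deriveSeed(config$seed, "filter"),
                de = .deriveSeed(config$seed, "de"),
                fitness = .deriveSeed(config$seed, "fitness"),
                eval = .deriveSeed(config$seed, "eval"))
  scores <- scoreFeatures(dataset, method = config$filter,
                          bins = config$bins, strategy = config$strategy,
                          reliefK = config$reliefK,
                          reliefSampleCount = config$reliefSampleCount,
                          reliefSign = config$reliefSign,
                          seed = seeds$filter)
  ranking <- rankFeatures(scores)
  red <- reduceDataset(dataset, ranking, config$fraction)
  mRed <- nFeatures(red$dataset)
  deResult <- NULL
  if (config$de@maxGenerations > 0L && mRed >= 2L) {
    fitFn <- makeFitnessFunction(red$dataset,
                                 classifier = config$fitnessClassifier,
                                 folds = config$fitnessFolds,
                                 seed = seeds$fitness)
    deCfg <- config$de
    deCfg@seed <- seeds$de
    deResult <- runDE(fitFn, mRed, deCfg)
    finalMask <- integer(nFeatures(dataset))
    finalMask[which(red$mask == 1L)[bestMask(deResult) == 1L]] <- 1L
  } else {
    finalMask <- red$mask
  }
  warning("features were selected and evaluated on the same samples; ",
          "reported accuracies are optimistically biased", call. = FALSE)
  evals <- lapply(config$evalClassifiers, function(clf) {
    suppressWarnings(crossValidate(dataset, finalMask, clf,
                                   folds = config$evalFolds,
                                   seed = seeds$eval))
  })
  names(evals) <- vapply(config$evalClassifiers, function(s) s@name,
                         character(1))
  structure(list(
    input = list(n = nSamples(dataset), m = nFeatures(dataset),
                 c = nClasses(dataset)),
    scores = scores, ranking = ranking,
    reducedCount = mRed, reduceMask = red$mask,
    deResult = deResult, finalMask = finalMask,
    selectedCount = sum(finalMask),
    selectedFeatures = featureIds(dataset)[finalMask == 1L],
    evaluations = evals, seeds = seeds, config = config),
    class = "RunReport")
}

#' @export
print.RunReport <- function(x, ...) {
  cat("Hybrid filter-DE run report\n")
  cat(sprintf("  input: %d samples x %d features, %d classes\n",
              x$input$n, x$input$m, x$input$c))
  cat(sprintf("  filter: %s -> %d features retained (top %.1f%%)\n",
              x$config$filter, x$reducedCount, 100 * x$config$fraction))
  if (!is.null(x$deResult))
    cat(sprintf("  DE: %d features selected, fitness %.4f (%d evaluations)\n",
                sum(bestMask(x$deResult)), bestFitness(x$deResult),
                x$deResult@evaluations))
  for (nm in names(x$evaluations))
    cat(sprintf("  %s 10-fold accuracy: %.2f%%\n", nm,
                x$evaluations[[nm]]$report@accuracy))
  invisible(x)
}

#' Compare filter/classifier configurations on one dataset
#'
#' Runs [runHybrid()] for each configuration and tabulates one row per
#' (filter, evaluation classifier) pair with the selected-feature counts
#' and the pooled cross-validated metrics.
#'
#' @param dataset an [ExpressionDataset-class]
#' @param configs list of [pipelineConfig()] objects
#' @return data.frame with columns `filter`, `classifier`,
#'   `reducedCount`, `selectedCount`, `accuracy`, `overallRecall`,
#'   `overallPrecision`, `overallFmeasure`, `error` (NA unless the run
#'   failed)
#' @export
compareMethods <- function(dataset, configs) {
  rows <- lapply(configs, function(cfg) {
    res <- tryCatch(suppressWarnings(runHybrid(dataset, cfg)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      return(data.frame(filter = cfg$filter, classifier = NA_character_,
                        reducedCount = NA_integer_,
                        selectedCount = NA_integer_, accuracy = NA_real_,
                        overallRecall = NA_real_,
                        overallPrecision = NA_real_,
                        overallFmeasure = NA_real_,
                        error = conditionMessage(res)))
    }
    do.call(rbind, lapply(names(res$evaluations), function(nm) {
      rep <- res$evaluations[[nm]]$report
      data.frame(filter = cfg$filter, classifier = nm,
                 reducedCount = res$reducedCount,
                 selectedCount = res$selectedCount,
                 accuracy = rep@accuracy,
                 overallRecall = rep@overallRecall,
                 overallPrecision = rep@overallPrecision,
                 overallFmeasure = rep@overallFmeasure,
                 error = NA_character_)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
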