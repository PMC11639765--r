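#' @importFrom withr with_seed
NULL

# Evaluate expr under a local RNG seeded with `seed`, restoring global state.
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stage sub-seed from the master seed.  Stages are numbered so each
# gets an independent, reproducible stream; the result stays below 2^31.
.deriveSeed <- function(master, stage) {
  idx <- match(stage, c("filter", "de", "fitness", "eval"))
  if (is.na(idx)) stop("unknown seed stage: ", stage)
  as.integer((as.numeric(master) + 1000003 * idx) %% (2^31 - 1))
}

# Stratified fold assignment: within each class the (shuffled) samples are
# dealt to folds cyclically, carrying the cycle position across classes so
# per-class counts differ by at most 1 per fold and so do total fold sizes.
.stratifiedFolds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("fold count must lie in [2, n]")
  fold <- integer(n)
  .withSeed(seed, {
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  fold
}

# Plain (unstratified) fold assignment, sizes differing by <= 1.
.plainFolds <- function(n, k, seed) {
  .withSeed(seed, {
    ((sample.int(n) - 1L) %% k) + 1L
  })
}

.checkMask <- function(mask, m = NULL) {
  if (!all(mask %in% c(0, 1)))
    stop("mask entries must be 0 or 1")
  if (!is.null(m) && length(mask) != m)
    stop(sprintf("mask length %d does not match feature count %d",
                 length(mask), m))
  as.integer(mask)
}
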