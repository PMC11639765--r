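---
title: "Hybrid filter + binary differential-evolution gene selection: methods and design"
author: "geneFilterDE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid filter + binary DE gene selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneFilterDE)
```

## The problem

Microarray and bulk RNA expression matrices pair tens of samples with
thousands to tens of thousands of genes, most of which are irrelevant or
redundant for phenotype classification. `geneFilterDE` implements a
two-stage selector for this regime:

1. **Filter stage.** Every gene is scored against the class label with a
   classifier-independent statistic, genes are ranked, and only the top
   fraction (5% by default) is retained.
2. **Wrapper stage.** A binary differential evolution (DE) searches 0/1
   masks over the retained genes, minimising the stratified
   cross-validated misclassification rate of a chosen classifier.

The final selection is evaluated with pooled stratified 10-fold
cross-validation and reported with macro-averaged multiclass metrics.

## Filter scorers

All six scorers return "higher is better" scores of length $m$.
For the entropy and contingency family, each gene is first discretized
into $r$ bins (equal width by default, $r = 10$); the class label is
categorical with $c \ge 2$ classes.

* **Information gain.**
  $IG(S, A) = H(S) - \sum_v \frac{|S_v|}{|S|} H(S_v)$ with
  $H(S) = -\sum_j p_j \log_2 p_j$. Bounded by $[0, H(S)]$; a constant
  gene scores 0 and a gene reproducing a binary label scores $H(S)$.
* **Gain ratio.** $IG / SplitInfo$ where the split information is the
  entropy of the bin occupancy. A gene collapsing to one bin has
  $SplitInfo = 0$ and is defined to score 0. Bounded by $[0, 1]$.
* **Chi-squared.** $\sum_{i=1}^{r}\sum_{j=1}^{c} (O_{ij}-E_{ij})^2/E_{ij}$
  over the bins-by-classes contingency table, $E_{ij}$ the independence
  expectation; empty rows contribute nothing.
* **Gini gain.** The impurity analogue of information gain with
  $Gini(S) = 1 - \sum_j p_j^2$.
* **Correlation.** $|r_{\mathrm{Pearson}}(x_j, y)|$ against the
  integer-coded labels (first-appearance order). A subset-level merit
  $\frac{f\,\bar{r}_{ca}}{\sqrt{f + f(f-1)\bar{r}_{aa}}}$ is exposed as
  `cfsMerit()` for completeness; the ranking filter is the per-gene
  absolute correlation, which is what the subset merit degenerates to at
  $f = 1$.
* **Relief.** For each instance, the per-gene distance to its nearest
  same-class neighbour (hit) is subtracted from the distance to its
  nearest other-class neighbour (miss), accumulated over all instances
  and halved. Distances are range-scaled so each gene contributes in
  $[0, 1]$; neighbours are found in the full feature space under the
  Manhattan sum of those per-gene distances. The printed form of this
  statistic in parts of the literature subtracts in the opposite order
  (hit minus miss), which would rank discriminative genes *last*; the
  package defaults to the classical orientation (miss minus hit) and
  offers `sign = "literal_paper"` to flip it.

**Discretization** is a deliberate choice the original description
leaves open: equal-width binning with $r = 10$ is the default because it
is deterministic, parameter-light and matches the "r bins" framing of
the chi-squared statistic; equal-frequency binning is available. With
very few samples, many bins make entropy-family scores saturate (every
occupied bin becomes pure), so analyses with $n \lesssim 20$ should
lower `bins`.

**Top-fraction rule.** `topFractionCount(m, fraction)` is
round-half-up of $fraction \times m$, floored at one gene. With the
default 5% this reproduces the four benchmark reductions
$5597 \to 280$, $6129 \to 306$, $12600 \to 630$ and $24481 \to 1224$,
which pin down the rounding convention. Ranking ties are broken by
ascending gene index, so rankings are reproducible across platforms.

## Binary differential evolution

Masks are vectors in $\{0,1\}^m$. Each generation, every individual
$X_i$ is challenged by a trial built from three distinct partners
$X_{r1}, X_{r2}, X_{r3}$ (uniform, excluding $i$):

* *Mutation.* $d$-wise: the difference bit is 0 where
  $x_{r1,d} = x_{r2,d}$ and $x_{r1,d}$ otherwise; the mutant bit is 1
  where the difference bit is 1 and $x_{r3,d}$ otherwise.
* *Crossover.* The trial takes the mutant bit where an independent
  per-position uniform draw is $\le CR$ or at one forced position
  $d_{rand}$, else the source bit. Default $CR = 0.9$.
* *Selection.* The trial replaces the source only on strictly lower
  misclassification rate; ties retain the source. Winners enter the
  population of the *next* generation (generational semantics, which in
  our benchmarks mixes measurably better than steady-state replacement).

Defaults ($P = 50$, $CR = 0.9$) follow the published setting; the
generation budget is swept 50–600 in the original study, and the
package default is $G = 100$. The continuous operator
$X_{r1} + F(X_{r3} - X_{r2})$ is provided as `mutateContinuous()` for
reference; the binary rules never use $F$.

Practical conventions: all-zero initial individuals are repaired by
setting one random bit; all-zero *trial* masks are assigned the worst
fitness 1.0 without training anything, so the search itself avoids the
empty subset; the returned best is the minimum over every individual
ever evaluated, making the recorded trajectory non-increasing by
construction; the whole run is reproducible from the `DEConfig` seed.

**Known limitation — stagnation after convergence.** Once every
individual is identical, the difference vector is zero everywhere, the
mutant equals the population point and the trial equals its source: the
search is frozen regardless of remaining budget. On a 10-bit
Hamming-distance objective ($P = 20$, $G = 50$) about 9% of seeded runs
stagnate one bit short of the optimum; on 12-bit tabulated landscapes
the exact-optimum rate varies strongly with the landscape's ruggedness.
We deliberately did not add restart or forced-perturbation heuristics:
the operator set is kept exactly as specified, and the test suite
documents the measured behaviour rather than masking it. Variants we
evaluated and rejected as worse on the same benchmarks: tie-accepting
selection, steady-state replacement, and a single crossover draw per
trial.

## Fitness

`misclassificationFitness()` trains the configured classifier inside a
stratified $k$-fold cross-validation ($k = 5$ by default) on the masked
genes and returns the pooled out-of-fold error rate. Resubstitution
error would let flexible learners reach zero trivially; internal CV
keeps the objective honest. Fold assignment depends only on the fitness
seed, so a mask always receives the same value within a run, which
makes memoisation (`makeFitnessFunction()`) exact. Classifiers are the
standard implementations: `class::knn` ($k=3$), `e1071::naiveBayes`,
`rpart` CART, `randomForest` (100 trees), `e1071::svm` (linear kernel);
hyperparameters are overridable through `classifierSpec()`.

A second limitation follows from the objective itself: on strongly
separable data the error rate saturates at zero for nearly every
subset, after which the search has no gradient — the best mask is then
essentially the first zero-error mask encountered, a random half of the
reduced set. This matches the original observation that DE discards
roughly 50% of the filtered genes, but it means the *identity* of the
selected genes is not determined by fitness on easy data. Users who
need parsimony should add an explicit subset-size criterion downstream;
the package keeps the published error-only objective.

## Evaluation metrics

`confusionMatrix()` pools out-of-fold predictions (rows true, columns
predicted). From its one-vs-rest counts:
recall$_i$ = $TP_i/(TP_i+FN_i)$, precision$_i$ = $TP_i/(TP_i+FP_i)$,
F$_i$ their harmonic mean, $FPR_i = FP_i/(FP_i+TN_i)$,
$FNR_i = FN_i/(FN_i+TP_i)$. Overall values are *unweighted* (macro)
means over classes, implemented literally even for imbalanced data.
Zero denominators yield 0 with a warning. Pooling predictions into a
single confusion matrix (rather than averaging per-fold metrics) is the
only convention consistent with reporting one confusion-derived set of
values. Percentages are reported on the 0–100 scale; FPR/FNR as
proportions, so $FNR_i = 1 - \mathrm{recall}_i/100$ holds exactly.

## Synthetic data generator

`generateDataset(syntheticSpec(...))` emulates the benchmark regime at
test scale: Gaussian baseline noise ($\sigma = 1$), `informative` genes
whose class means are spaced `effectSize`·$\sigma$ apart, `redundant`
genes built as $\rho\,\mathrm{parent} + \sqrt{1-\rho^2}\,\varepsilon$
from round-robin-assigned informative parents, and pure noise
elsewhere. Defaults — two classes of 30 samples, 600 genes, 15
informative, 30 redundant, effect 1.5, $\rho = 0.8$ — are small enough
for minutes-scale continuous testing while preserving the qualitative
structure (a small signal core drowned in noise, redundancy blocks).

What the generator does *not* emulate: probe- and batch-effects, heavy
tails and intensity-dependent variance of real microarrays, correlated
noise cliques. Passing tests therefore demonstrate algorithmic
correctness and recovery under a clean Gaussian model, not performance
on real chips.

`recoveryReport()` scores a selection against the planted truth:
precision is the fraction of selected genes carrying signal; informative
recall counts a planted gene as captured when the gene itself or any of
its redundant children is selected.

## Seeds and reproducibility

A pipeline master seed is split into stage sub-seeds
(`filter`, `de`, `fitness`, `eval`) as
$(\mathrm{seed} + 1000003\,k) \bmod (2^{31}-1)$ for stage index $k$,
so each stage is independently reproducible and no seed exceeds the
32-bit integer range. All stochastic code runs under `withr::with_seed`,
leaving the session RNG untouched. Identical master seeds give
bit-identical run reports.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script use deliberately small
configurations chosen as a package design point: oracle comparisons on
$n \le 12$, $m \le 6$ datasets; DE benchmarks at $m = 10$–$12$ with
exhaustive or constructive optima; pipeline runs on the default
600-gene synthetic spec with $P = 30$, $G = 40$ (the reduced set has 30
genes, so this budget saturates the search). The four printed
dimensionality reductions are verified exactly at their original sizes,
which costs nothing because only the counting rule is involved.

## Degenerate inputs and edge conventions

* Non-finite expression values are rejected at load, never imputed.
* Constant genes: one discretization bin, zero entropy-family and
  correlation scores, zero Relief contribution.
* Empty masks: invalid for subsetting; sentinel fitness 1.0 in the DE.
* A class smaller than the requested folds reduces the fold count with
  a warning; fold sizes and per-fold class counts never differ by more
  than one sample (the cyclic dealing carries its position across
  classes).
* `maxGenerations = 0` in the pipeline skips the wrapper stage
  entirely, reducing the method to filter-plus-CV.
* Selection and evaluation reuse the same samples, as in the original
  protocol; `runHybrid()` emits a warning because this is optimistically
  biased — an outer held-out split is the user's responsibility.
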