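---
title: "Wrapper feature selection for expression biomarkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper feature selection for expression biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasvm)
```

## The problem

Case/control expression studies ask two related questions: which genes
separate the two phenotypes, and which *small combinations* of genes do so
together. Univariate rankers answer the first question but tend to return
highly redundant lists — when a family of correlated genes separates the
classes, every member scores well, and combining them adds little. This
package implements a wrapper selector that addresses the second question: a
genetic algorithm (GA) evolves small gene subsets scored by the
cross-validated accuracy of a Gaussian-kernel support vector machine (SVM)
trained on exactly those genes. Because every candidate subset is scored as
a *unit*, redundant genes compete for the same slot while complementary
genes reinforce each other.

## The selection model

A candidate solution ("chromosome") is a boolean inclusion mask over a
candidate pool of `N` genes. Its fitness is

```
fitness = (1 - w) * accuracy + w * (N - n) / N
```

where `accuracy` is the mean six-fold internally cross-validated accuracy of
a Gaussian-kernel SVM trained on the `n` selected genes, and the second term
rewards parsimony. The weight `w = 0.2` keeps accuracy dominant; the
parsimony term resolves ties between equally accurate subsets in favour of
the smaller one. The SVM runs at libsvm defaults — regularisation constant
1 and kernel coefficient `1/n` — with no feature rescaling and no tuning.

Evolution follows a fixed protocol per generation: 160 offspring are
produced by roulette-wheel parent selection and uniform crossover, 20
additional mutants are bit-flipped copies (rate 0.0015 per bit) of
roulette-selected chromosomes, and the best 200 of the pooled
200 + 160 + 20 = 380 chromosomes survive. Mutants are added as extra
copies, not edited in place — the pool arithmetic forces that reading.
After 25 generations the best chromosome's gene set is returned. Elitist
truncation makes the best fitness non-decreasing, which the tests assert
per run.

A single run returns one small set. Importance scores comparable to
univariate rankers come from repeating the run (200-3,000 times at full
scale) and counting how often each gene appears in the final sets
(`ga_svm_runs()`). Within a run the internal CV split is drawn once,
stratified by class, and frozen, so fitness values can be cached by mask;
the cache would be invalid under per-evaluation resplitting.

Two open choices were fixed as follows: roulette selection uses raw (not
rank-scaled) fitness, and the 20 mutation sources are drawn with
replacement. An empty chromosome (possible after crossover of sparse
parents) is assigned fitness 0 rather than raising, so evolution proceeds.

## Preprocessing and cross-validation design

The candidate pool is built from a genome-scale matrix by: averaging probes
per gene symbol (`aggregate_probes()`); a per-gene two-sided Welch t-test
with Benjamini-Hochberg correction, dismissing genes with an FDR estimate
above 0.1 (`welch_fdr_filter()`); and ranking the survivors by fold change
— the difference of class means on the log scale — truncated to the top
1,000 (`rank_by_fold_change()`). The fold-change sort uses the *absolute*
value by default: a signed sort would silently exclude down-regulated
markers, and strongly down-regulated genes are as informative as
up-regulated ones. A `signed = TRUE` flag restores the signed ordering.
Zero-variance genes get `p = 1` (logged) instead of an error so degenerate
synthetic inputs flow through.

Evaluation uses subject-grouped folds (`make_grouped_folds()`): all samples
of one subject land on the same side of every split, because samples from
one brain are correlated and splitting them across train and test would
leak. Subjects are dealt greedily so per-fold class counts differ by at
most one subject and stratum (brain-region) proportions stay as even as the
integers allow; the greedy rule is this package's choice since no exact
algorithm is prescribed by the protocol. Filtering is computed per training
fold for evaluation workflows, and once on all samples when the goal is the
final biomarker ranking.

The test suite carries a deliberate-leak canary: on pure-noise data, a
ranking computed on *all* samples before the split must outperform the
honest per-fold ranking. Note that a ranking computed on the held-out fold
*alone* is not a usable canary — the training data still sets the decision
direction of the classifier, so the inflation cancels on average; the
all-samples form is the classic selection leak and is what the tests use.

## Baseline rankers

*Information gain* discretizes each gene by Fayyad-Irani MDL recursive
binary splitting (the default supervised discretization of the Weka family
of tools) and scores `H(class) - H(class | bins)` in bits. The cut search
evaluates every midpoint between adjacent distinct values, so the score is
invariant under monotone transformations, and the method is fully
deterministic. A fixed equal-frequency binning fallback is available. Genes
with no MDL-accepted cut score 0.

*Random forest* importance is mean decrease accuracy: per tree, out-of-bag
samples are classified before and after permuting one gene's values, and
the decrease in correct classifications is averaged over 1,000 trees, then
over three independently grown forests to damp its variance. Trees grow to
purity with `ceiling(sqrt(m))` candidate genes per split. The
`randomForest` package provides the forests; the reported score is its
unscaled permutation importance, which matches this definition up to the
per-tree OOB normalisation.

Rankings are combined by averaging each gene's *rank* (not score) across
methods (`combine_ranks()`); a gene absent from one list gets that list's
length + 1. All ties anywhere break by gene symbol, for reproducibility.

## Gene-pair interaction analysis

Across `R` repeated GA/SVM runs, let `k_i` count the sets containing gene
`i` and `k_ij` the sets containing both `i` and `j`. Under independence the
expected joint count is `k'_ij = k_i * k_j / R`; the representation score is
`importance_jo = log(k_ij / k'_ij)` (natural log — only the ordering is
used downstream). Significance comes from the chi-square statistic (1 df,
no continuity correction) of the full 2x2 presence/absence table over the
`R` sets, whose (both, both) expectation is exactly `k'_ij`; p-values are
BH-corrected at FDR 0.05 across the pairs whose expectation exceeds 5. The
expectation filter is applied *before* the correction, and pairs that never
co-occur (`k_ij = 0`) are enumerated too when their expectation passes the
filter — they are the strongest under-representation signal, reported with
a `-Inf` score sentinel and placed last among under-represented pairs.

Pair quality is measured by three Gaussian-SVM accuracies under one frozen
stratified 10-fold split — gene `i` alone, `j` alone, and the pair — giving
`gain_mean = acc_ij - (acc_i + acc_j)/2` and
`gain_min = acc_ij - max(acc_i, acc_j)`. Reusing one split across the three
fits keeps the gains from being split-noise artifacts.
`accumulate_top_pairs()` reports running means of these quantities along
the pairs sorted by representation strength, per direction. The
accumulation grid defaults to 3, 6, ..., 75; desk-scale studies produce far
fewer significant pairs than a 3,000-run full-scale analysis, so the
bundled tests use a step-1 grid over the handful of available pairs — the
grid is a resolution parameter, not part of the statistic.

## Redundancy profiling and enrichment

Mutual information between two genes is estimated by equal-frequency
discretization (10 bins by default, fewer when a gene has too few distinct
values) and the plug-in estimator, in bits. The plug-in estimator is
positively biased at these sample sizes, so absolute values are not
interpretable — only comparisons between gene lists profiled the same way,
which is how the package uses them (the wrapper's top list should carry
less pairwise MI than the univariate rankers' lists).

Over-representation of a selected set in a reference list uses the
upper-tail hypergeometric probability within a stated gene universe (all
genes on the platform; for synthetic runs, all generated genes). Each
(list, size) cell of a sweep is reported with its raw p-value — no
correction across the grid, matching the three-state presentation
(significant / enriched / not enriched) the sweep mirrors; treat the grid
as descriptive, not confirmatory.

## The synthetic generator

`simulate_expression()` emulates the structure of a multi-region two-class
brain expression study at desk scale: subjects carry the class label (all
samples of a subject share it), every subject contributes one sample per
stratum, and each gene value sums a class shift (informative genes), a
shared latent block signal (redundancy-block members), a per-(subject,
gene) random intercept, and Gaussian noise. The block mixing weight is
solved from the target within-block correlation
(`lambda = noise_sd * sqrt(rho / (1 - rho))`). Informative shifts alternate
in sign so panels contain both up- and down-regulated markers. An optional
`block_effect_size` lets a block carry a class shift as well — redundant
*and* informative families are exactly what the redundancy analyses probe,
and without it blocks would be pure noise. No real-data value is available
for the within-subject correlation, so `subject_effect_sd` defaults to 0.5
(an intra-class correlation of 0.2 against unit noise), exposed in the
configuration.

What the generator does **not** emulate: probe-level structure, batch and
array effects, heavy-tailed or skewed noise, mean-variance coupling, and
genome-scale correlation networks. Passing tests therefore demonstrate that
the algorithms behave as specified under controlled conditions, not that
any particular biological dataset will yield the same lists.

Problem sizes in the bundled studies were chosen to keep a complete run on
one desk CPU comfortable: recovery study 500 genes x 120 samples with 50
wrapper runs (population 60, 12 generations, initial inclusion rate held
at the published 1.5 percent); redundancy and synergy studies of 110 and 38
genes with 200 reduced runs each. One caveat observed consistently in the
recovery study: truncating the protocol to 12 generations leaves a minority
of runs with final sets of 16-19 genes. The published small-set sizes (up
to ~15) are a property of the full 25-generation protocol, whose later
generations prune accuracy-neutral passenger genes; a truncated run is
still mid-pruning, and freezing the internal CV split (required for valid
fitness caching) lets lucky passengers persist longer.

## Numerical and degenerate-input conventions

* Welch test with zero pooled variance: `p = 1`, logged, never an error.
* BH q-values via `stats::p.adjust`; agreement with an independent
  implementation to 1e-10 is a test invariant.
* Chi-square on 2x2 tables without Yates correction; `chisq.test`
  equivalence to 1e-9 is asserted.
* Roulette selection with an all-zero fitness vector falls back to a
  uniform draw (logged).
* All RNG flows through R's generator from explicit seeds; per-stage seeds
  in the pipeline derive from the global seed plus the stage name, so
  adding a stage never shifts another stage's stream. libsvm's own
  cross-validation mode is avoided because its internal shuffle is not
  reproducible from R.
* Ties: gene symbol order everywhere; fold-change ties additionally prefer
  the smaller q-value.

## Known limitations

The wrapper's runtime is dominated by SVM fits (hundreds of thousands per
full-scale study); the package caches fitness by mask within a run but does
not parallelise across runs. The MI estimator is biased and only used
comparatively. The enrichment sweep reports raw p-values per cell. The
generator's Gaussian, batch-free world is favourable to every method
tested; relative comparisons between methods are the meaningful output.
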