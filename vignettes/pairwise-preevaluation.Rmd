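---
title: "Pairwise pre-evaluation for feature selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise pre-evaluation for feature selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Expression profiling experiments produce matrices with tens of thousands of
features (probes, genes) and a few dozen to a few hundred labelled samples.
Selecting a small informative feature subset is essential both for
classification accuracy and for interpretation, but the subset space is
astronomically large: a 1000-feature dataset has
$2^{1000} \approx 1.07\times10^{301}$ candidate subsets
(`subset_space_size(1000)` computes this exactly), so exhaustive search is
out of the question. The two practical families both have a blind spot:

* **Filters** (Chi-squared, Gain ratio, ReliefF, FSDD) score each feature
  *independently* against the class. They are fast but cannot see
  feature–feature interactions.
* **Wrappers** (forward search, backward elimination) score whole subsets
  with a classifier, so they can in principle exploit interactions, but
  greedy forward search builds subsets one feature at a time — a pair that
  only works *jointly* is never tried.

The idea implemented here is a middle path: all $\binom{N}{2}$ feature
pairs *can* be evaluated (499,500 for $N = 1000$). The package builds a
**pair table**: for every unordered pair $(i, j)$ the cross-validated
accuracy $v_{ij}$ of a classifier trained on exactly those two features,
sorted by $v_{ij}$ descending. The top-ranking pairs are then injected into
the classic selectors:

* `pairwise_reorder()` permutes a filter ranking: pop the head feature of
  the original ranking, then scan the top-$T$ pair rows in table order and
  pull each partner of the popped feature up right behind it; repeat until
  the ranking is exhausted.
* `modified_forward_search()` replaces single-feature candidate moves with
  moves generated by the top-$T$ pair rows (adding the 1 or 2 features of a
  row not yet chosen), so an interacting pair enters in one step.
* `modified_backward_elimination()` starts from the union of features in
  the top-$T$ rows — an interaction-aware pre-selection that collapses the
  search — and prunes it greedily.
* `modified_mrmr()` scores the same pair-derived moves with the mRMR MID
  criterion (relevance minus mean redundancy, on mutual information) and
  accepts the best move unconditionally until exactly $m$ features are
  collected.

## The pipeline

`run_pipeline()` (or the `inst/scripts/pairsel` command line) chains:

1. **Pre-filtering** (`prefilter_top_n()`): plug-in mutual information on
   discretized codes keeps the best $n$ features (1000 is the conventional
   choice for microarray matrices) so the quadratic pair-table stage is
   tractable.
2. **Pair table** (`build_pair_table()`): every pair evaluated by LOOCV;
   chunked enumeration makes the result bit-identical for any worker count.
   The table is cached keyed on the dataset and configuration hash, because
   it is by far the most expensive stage and is built once per dataset.
3. **Selection**: original and/or pair-table-modified selectors.
4. **Evaluation** (`accuracy_profile()`): LOOCV accuracy of the first
   5, 10, ..., 30 ranked features per classifier, the standard reporting
   grid, plus per-column maxima (`profile_table()`).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_bins`, `strategy` | 5, equal frequency | discretization for MI, Chi-squared, Gain ratio, mRMR. Equal frequency with inverse-ECDF edges is invariant to monotone transforms and robust for skewed expression values. |
| `eval_config(classifier=)` | `svm_linear`, C = 1 | pair-table and wrapper evaluator; also `knn` (k = 3), `naive_bayes`, `random_forest` (100 trees). Features are standardized with training-fold statistics only. |
| `cv` | `loocv` | leave-one-out; stratified k-fold offered as a fast mode for large matrices. |
| `top` / `top_pairs` ($T$) | 1000 | number of leading pair rows the modified methods consult. Calibrated to $N = 1000$ (top 0.2% of 499,500 rows); for desk-scale tables scale it down accordingly (the tests use $T = 100$ on ~50–75-feature tables). |
| `beta` (FSDD) | 2 | weight of the within-class variance penalty. |
| `k_neighbors` (ReliefF) | 3 | neighbours per class; the deterministic full pass over all instances is used rather than random sampling. |

Numerical conventions, chosen for determinism: all score ties break towards
the lower feature index; pair rows tie-break by ascending pair position;
kNN breaks distance ties by training-row index and vote ties by the lowest
class label; the SVM dual coordinate descent visits samples in a fixed
cyclic order (tolerance $10^{-3}$, at most 1000 passes); the random forest
draws all randomness from the `eval_config` seed. Forward search starts
from an empty set with baseline accuracy 0 (so the first accepted move is
the best singleton — or the best pair in the modified variant) and accepts
strict improvements only; backward elimination accepts accuracy-preserving
removals so it can pass through redundant plateaus. Constant features
discretize to a single code, get Gain ratio 0 by the $H(F)=0$ convention,
and survive standardization as all-zero columns.

## The synthetic world

`generate_dataset(synthetic_spec(...))` plants four feature roles in a
Gaussian matrix: *univariate* features whose class means are separated by
`effect_size` SD; *XOR pairs* $(x, y)$ with class $= \mathrm{sign}(x y)$ —
each member is marginally independent of the class, the canonical
interaction invisible to every univariate filter; *redundant* noisy copies
of univariate features (co-regulated probes); and pure *noise*. Labels can
be flipped at a given rate. The generator is deterministic given the spec
and restores the caller's RNG state.

What the generator does **not** emulate: heavy-tailed intensity
distributions, probe-level correlation structure beyond exact parent–copy
pairs, batch effects, and class-imbalanced designs. A green test on this
world therefore establishes algorithmic correctness and the stated
interaction-recovery mechanisms, not performance on real microarray data.

## Choice of the pair-table evaluator

The default pair-table classifier is the linear SVM (deterministic, fast,
and the conventional reporting classifier). One consequence matters for
interaction studies: **a linear decision function cannot express the XOR
construct** — on a planted pair the two-feature linear SVM scores at or
below chance (measured ≈ 0.28 LOOCV), while 1-NN/3-NN score ≈ 0.95. Pair
tables intended to surface interactions must therefore be built with an
interaction-capable evaluator; the interaction tests in this package use
`eval_config("knn")`. This mirrors the general caveat that the pair table
inherits the representational bias of its evaluator.

## What the reorder can and cannot do

`pairwise_reorder()` follows the pop-and-pull procedure exactly: a feature
is promoted only when a top-$T$ row links it to an *already placed*
feature. This promotes complements of strong features (a feature useless
alone but excellent jointly with the current leader is pulled up right
behind it). It provably cannot promote a pair whose **both** members lack
marginal signal: neither member is ever popped early, and their only
high-accuracy row links them to each other. In simulations with planted
XOR pairs the pair's row tops the table in 10/10 seeds and the modified
forward search (whose moves are whole rows) captures the pair as its first
accepted move in 10/10 seeds, yet the reordered Chi-squared ranking never
lifts the members into the top 10 (0/10). Likewise, on independent-Gaussian
synthetic data the reordered top-25 is on average no better than the
original top-25 (measured 0.857 vs 0.871 over 20 seeds): with independent
features, "pairs well with the leader" carries no information beyond the
univariate score, so reordering only reshuffles the noise margin. Two
acceptance checks encode these two outcomes as aspirations of the reorder
and are deliberately left failing rather than weakened; the mechanism that
does recover buried interactions in this package is the modified forward
search (and modified mRMR), not the filter reorder. On real expression
data, where informative genes are co-expressed and complementarity is
widespread, the reorder has more structure to exploit — which is consistent
with published gains on microarray benchmarks being largest for the filter
methods.

## Design decisions taken where the procedure was open

* **Reorder semantics.** Pulled partners are appended once (the popped
  feature is already placed), duplicates skipped; partners follow pair-row
  order. $T$ is an explicit parameter because the untruncated table would
  let the first popped feature pull in every other feature.
* **Modified forward moves** may overlap the chosen set by one feature;
  this is what makes odd-sized selected subsets possible, matching the
  odd subset sizes reported for the method on real data.
* **Modified backward initialization** from the top-$T$ pair union is the
  step that reproduces the reported ~90% feature reduction; it is isolated
  in one operation so alternative initializations can be swapped in.
* **Modified mRMR truncation**: a final two-feature move that would
  overshoot $m$ contributes only its higher-relevance member, and members
  of an accepted pair are listed higher-relevance first.
* **Empty-set baseline 0** for forward search; backward accepts ties.
* **MI estimator**: discretized plug-in, log base 2. No bias correction —
  scores are only compared between features estimated identically.
* **FSDD** uses $J = \sum_c p_c(\mu_c-\mu)^2 - \beta \sum_c p_c\sigma_c^2$
  on z-normalized features with $\beta = 2$, the standard
  distance-discriminant form, since only the verbal description is fixed.
* **Pair-table files** print accuracies with 6 decimals; re-reading a
  written table reproduces rows and printed values exactly, and files use
  feature *names*, never bare indices, to avoid off-by-one ambiguity.

## Known limitations

* The pair-table stage is $O(N^2)$ LOOCV fits; at $N = 1000$ and a few
  hundred samples it is minutes-to-hours of compute (use `workers`).
* No redundancy removal inside the modified methods: a pair table rewards
  pairs of strong, possibly mutually redundant features.
* Triples and higher-order interactions are out of scope.
* LOOCV accuracies on small $n$ are coarse (multiples of $1/n$), so
  plateau ties are common; the deterministic tie-breaking makes results
  reproducible but not unique in any deeper sense.

## A worked example

```{r, eval = FALSE}
library(pairsel)

sim <- generate_dataset(synthetic_spec(
  n_samples = 100, n_univariate = 5, effect_size = 1,
  n_xor_pairs = 1, n_redundant = 0, n_noise = 24, seed = 11))

pt <- build_pair_table(sim$data, config = eval_config("knn"))
head(tidy(pt))           # the planted pair tops the table
fs <- modified_forward_search(sim$data, pt, top = 50,
                              config = eval_config("knn"))
tidy(fs)                 # first accepted move: the planted pair
```
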