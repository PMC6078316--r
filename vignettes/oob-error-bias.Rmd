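---
title: "Why the out-of-bag error of a subsampling forest is pessimistic, and what to do about it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why the out-of-bag error of a subsampling forest is pessimistic, and what to do about it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oobias)
```

## The problem

The out-of-bag (OOB) error is the default, almost-free error estimate of a
random forest: every tree is grown on a random subsample of the training
rows, so every row is left out ("out-of-bag") by some of the trees, and a
prediction for that row can be formed by majority vote over exactly those
trees. Averaging the resulting misclassification indicator over the training
set gives the OOB error, and it is routinely treated as an unbiased stand-in
for the error on new data — both for reporting performance and for picking
tuning parameters such as `mtry`, the number of candidate predictors drawn
at each split.

For classification with metric predictors this trust is misplaced in a
specific, predictable set of circumstances. When the training sample is
small, the class distribution of a without-replacement subsample of size
$\lfloor 0.632\,n \rfloor$ fluctuates around the training distribution, and
classification trees are notoriously sensitive to that fluctuation: a tree
grown on a subsample in which class 2 happens to dominate will preferentially
predict class 2. For a *new* observation these preferences average out across
trees. For an *OOB* observation they do not: conditional on row $i$ (say,
from class 1) being excluded from a subsample, the subsample contains
relatively fewer class-1 rows, so the trees voting on $i$ are exactly the
trees tilted toward the wrong class. The OOB error is therefore biased
upward, most strongly when

* the classes are (nearly) balanced,
* $n$ is small,
* the number of predictors $p$ is large relative to the signal, and
* predictors are weakly correlated and effects are weak.

In the flagship high-risk setting implemented here — a balanced binary null
case with $n = 20$ and $p = 1000$, where the true error of any classifier is
exactly $0.5$ — the mean OOB error ranges between roughly $0.60$ and $0.75$
depending on `mtry`, an overestimation of 10 to 30 percentage points, while
the mean test error sits at $0.500$. Ten-fold cross-validation inherits the
same bias (the CV training splits are unbalanced by the same mechanism);
stratified variants of either estimator remove most of it.

This package implements the machinery to reproduce, dissect and repair the
bias: a subsampling forest with exact in-bag bookkeeping, three per-tree
sampling schemes, five error estimators, the hypergeometric theory of
subsample class composition, class-preference diagnostics, and seeded study
drivers.

## The forest

`subforest()` fits the ensemble studied throughout: `ntree` CART-style
trees, each grown to full size (nodes split until pure or unsplittable) on a
without-replacement subsample, with the best Gini-impurity split among
`mtry` uniformly drawn candidate predictors taken at every node. Tree
induction is delegated to the `ranger` engine, but the in-bag sets are drawn
by this package and handed to the engine verbatim, so the OOB bookkeeping —
which rows are out-of-bag for which tree — is exact and replayable, not
reconstructed after the fact. All randomness is consumed from R's global RNG
(the engine seed itself is drawn from it), so `set.seed()` reproduces a
forest bit for bit.

The three sampling schemes (`sampling_scheme()`):

| kind | per-tree in-bag sample |
|---|---|
| `unstratified` | uniform subset of size $\lfloor 0.632\,n \rfloor$ |
| `stratified` | same total, apportioned to classes proportionally to class sizes |
| `balanced` | $\lfloor 0.75\,n_{small} \rfloor$ from *every* class |

0.632 is the classical subsample size matching the expected number of
distinct observations in a bootstrap sample; for the balanced scheme the
larger fraction 0.75 of the smallest class is used because
$0.632\,n_{small}$ would leave very few training rows per tree when the
minority class is small. Stratified apportionment uses the largest-remainder
rule, so per-class counts deviate from exact proportionality by less than
one observation; the balanced scheme removes class-composition variability
altogether, at the price of discarding majority-class rows.

Forest votes are aggregated by majority with a deterministic tie rule
(smallest class label; configurable to random). With `ntree = 500` or 1000
exact vote ties are rare but possible, and a deterministic rule keeps study
replays byte-identical.

## The five estimators

For a fitted forest and its training data the package computes
(`test_error()`, `oob_error()`, `cv_error()`):

* **TEST** — misclassification on an independent sample from the same
  distribution; the gold standard the others are judged against.
* **OOB** — per-row majority vote over the trees for which the row is
  out-of-bag. Rows that are in-bag for every tree carry no OOB information
  and are excluded (with `ntree` in the hundreds the probability of such a
  row is negligible, about $0.632^{ntree}$).
* **STRAT_OOB** — the same computation on a forest whose subsamples were
  stratified; this is what removes the bias.
* **CV / STRAT_CV** — 10-fold cross-validation with plain or stratified
  folds. The reported CV error is the *unweighted* mean of the 10 fold error
  rates (the pooled per-observation error is also derivable from the
  report's fold components); class-specific CV errors are pooled over folds
  because per-fold class counts can be 0 or 1.

Every report carries class-specific errors, and the class-count-weighted
mean of the class-specific errors reproduces the overall error exactly
(checked as an invariant in the test suite).

Stratified folds are built by dealing each class's shuffled rows round-robin
across folds, which guarantees fold sizes within one of each other and
within-fold class counts within one across folds. If a class is smaller than
the number of folds, some folds will miss it — the constructor warns, and
`cv_error()` refuses a fold whose training complement lacks a class
entirely, naming the fold, rather than silently retrying.

## The mechanism, exactly

The class composition of an unstratified subsample is hypergeometric: drawing
$m$ of $n_1 + n_2$ rows without replacement, the number $X$ of class-1 rows
has
$$P(X = x) = \binom{n_1}{x}\binom{n_2}{m-x}\Big/\binom{n_1+n_2}{m}.$$
`subsample_class_pmf()` computes this exactly; `empirical_composition()`
validates it by Monte-Carlo and shows that the stratified and balanced
schemes collapse it to a point mass. For a balanced sample of $n = 20$
($m = 12$) the probability that a subsample is *not* perfectly balanced is
$1 - P(X = 6) \approx 0.650$; for $n = 100$, $m = \lfloor 0.632 \cdot 100
\rfloor = 63$ is odd, so every subsample is unbalanced with certainty. Note
that such statements are sensitive to the rounding convention for $m$:
quoted chances of roughly "50%" for $n = 20$ and "84%" for $n = 100$
circulate, which correspond to neither the floor convention nor the exact
pmf; the package always reports the exact values under
$m = \lfloor 0.632\,n\rfloor$ (`prob_unequal_composition()` returns 1 for
odd $m$ by parity).

The downstream symptom is quantified by `preference_fraction()` and
`run_preference_study()`: forests trained on 10-vs-20 null data predict the
minority class for a balanced test set with frequency far below one half,
the more extremely the smaller `mtry` and the larger $p$. With `mtry = 1`
there is no candidate selection at all, splits are pure noise, and the trees
regress to in-bag majority voting — on 10-vs-20 data the minority class
essentially disappears from the predictions. This is also why, for
*balanced* training data, the OOB bias grows as `mtry` shrinks, while for
unbalanced data small `mtry` drives both OOB and test error toward the
minority share (predicting the majority class constantly misclassifies
exactly the minority fraction — a useful analytic anchor: a constant
majority-class classifier on a 30%-minority test set errs at exactly
0.300).

## Consequences for tuning mtry

`tune_mtry()` selects the grid value with the smallest OOB error (ties to
the smallest `mtry`, which is the cheaper model; the selection rule is
deliberately deterministic). Two ways of then *reporting* an error are
implemented:

1. **Procedure 1** — report the minimum OOB error found during the search
   (`error_p1`). The same numbers are used to select and to report, so this
   estimate is optimistically biased.
2. **Procedure 2** — rebuild a freshly seeded forest at the chosen `mtry`
   and report its OOB error (`procedure2_error()`). The selection optimism
   is gone; only the scheme-inherent OOB bias remains.

`run_tuning_bias_study()` compares both procedures against the test error
under unstratified and stratified sampling;
`run_tuning_consequence_study()` asks the practical question — does
selecting `mtry` by a biased estimator actually pick worse classifiers? —
by selecting with each of the four data-reuse estimators and scoring the
resulting forests on independent test data.

## What the generators emulate — and what they do not

`simulation_design()` + `generate_dataset()` reproduce the simulation
designs of the underlying study: i.i.d. $N(0,1)$ predictors; in power cases
the first `n_effect` predictors get class-conditional means drawn once per
repetition from $N(\mu_0, 1)$ with $\mu_0 \in \{0.75, 0.4, 0.1\}$ depending
on the setting (class 1 is always the zero-mean reference, and the test set
of a repetition shares the training set's realized means). Class ratios are
exact by largest-remainder rounding — 50:50, 70:30 ($n = 30$: 21/9), 1:5
($n = 60$: 50/10). `permute_response()` and `permute_each_predictor()`
implement the two permutation nulls used to dissect real data: break the
predictor–response link while keeping the correlation structure, or
additionally break inter-predictor correlation column by column.

`generate_correlated_dataset()` is a synthetic stand-in for high-dimensional
expression matrices: block-exchangeable correlation (`rho` within
consecutive blocks, independence across), labels independent of features.
Real microarray data have heavier tails, unequal block sizes and long-range
correlation, none of which is modeled; passing tests on this generator shows
that the estimators behave as designed under correlated Gaussian nulls, not
that any particular real data set will show a bias of a particular size.
`draw_training_subset()` (rejection sampling with a minimum of 8 rows per
class, mirroring the real-data protocol) and `match_test_distribution()`
(largest remainder subset in the exact training class ratio) complete the
real-data-style pipeline for any externally supplied feature table
(`read_labeled_dataset()`).

The "many predictors with effect" variant has no published exact design; it
is expressed here simply as a `simulation_design` with `n_effect` close to
`p`, and the tuning studies default to the weak-effect high-dimensional
power case (`n_effect = 50`, $\mu_0 = 0.1$, $p = 1000$) so that errors stay
in a regime where the procedures can actually be distinguished. With
hundreds of effect predictors whose means are drawn with scale 1 the classes
become almost perfectly separable at $n = 20$ and every estimator collapses
to near zero, which demonstrates the orderings only degenerately.

## Study scales and numerical choices

The full-scale protocol (`ntree = 1000`, 500 repetitions, test sets of
10000) is configurable everywhere but is not the default: the bundled
studies and the acceptance script run a desk-scale profile — 50 repetitions,
`ntree = 500`, test size 2000 — chosen so that every Monte-Carlo mean has a
standard error well inside the tolerances being checked (for a mean error
over 50 repetitions the MC standard error is about $0.17/\sqrt{50} \approx
0.024$ per mtry value, and far smaller after averaging over a 14-point
grid). Per-repetition RNG streams are spawned from one master seed by a
single documented `sample.int` call (`rep_seeds()`), so any repetition can
be replayed in isolation and results do not depend on execution order.

Other deliberate choices, in one place:

* split-candidate ties inside a tree follow the engine's draw order;
  forest-vote ties go to the smallest class label (configurable);
* stratified apportionment and class-ratio rounding both use the
  largest-remainder rule, remainder ties to the earlier class;
* `tune_mtry` ties go to the smallest grid value;
* non-evaluable OOB rows are dropped from the error, never imputed;
* failed study cells (for example a CV fold losing a class under extreme
  imbalance) are recorded in the result table with their message in the
  `status` column and do not abort the run.

## Limitations

Bootstrap (with-replacement) resampling, conditional-inference trees,
variable importance, probability forests and AUC-based evaluation are out of
scope. The forest handles metric predictors only — with categorical
predictors the split-selection bias of exhaustive-search CART would
interact with the phenomena studied here. The bias quantifications shipped
in the tests are Monte-Carlo statements at desk scale about the implemented
generators; they transfer to real data qualitatively (the mechanism is the
same) but not numerically.
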