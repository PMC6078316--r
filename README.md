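# oobias — out-of-bag error bias in subsampling random forests

The out-of-bag (OOB) error is the standard "free" error estimate of a random
forest: each tree is grown on a without-replacement subsample of
⌊0.632 n⌋ training rows, and every row is classified by majority vote over
the trees that did *not* see it. For classification with metric predictors
this estimate can be substantially **pessimistic** — in small, (nearly)
balanced, high-dimensional samples the mean OOB error exceeds the true
error by 10–30 percentage points, with the size of the bias depending on
`mtry` (the number of candidate predictors drawn per split). The mechanism
is the class composition of the subsamples: the number of class-1 rows in a
subsample of size *m* drawn from class sizes *n₁*, *n₂* is hypergeometric,

P(X = x) = C(n₁, x) · C(n₂, m − x) / C(n₁ + n₂, m),

so small samples frequently yield unbalanced subsamples; trees grown on
them preferentially predict their in-bag majority class, and a row's OOB
trees are, by construction, exactly the trees tilted against its own class.
Drawing the subsamples *stratified* (per-class counts proportional to class
sizes) removes most of the bias; drawing *equal* numbers per class
(⌊0.75 n_small⌋, the balanced forest) additionally equalizes class-specific
errors on unbalanced data.

This package is a tested, seeded re-implementation of that entire study
programme for biostatisticians who use OOB estimates on n ≪ p data
(e.g. omics classification):

* `subforest()` — subsampling forest (fully grown Gini CART trees, `mtry`
  candidates per split, tree induction via **ranger**) with exact per-tree
  in-bag bookkeeping and three sampling schemes
  (`unstratified` / `stratified` / `balanced`);
* `test_error()`, `oob_error()`, `cv_error()` — the five estimators (test,
  OOB, stratified OOB, 10-fold CV, stratified 10-fold CV) with
  class-specific errors;
* `simulation_design()`, `generate_dataset()`, `generate_correlated_dataset()`,
  `permute_response()`, `permute_each_predictor()` — null/power generators,
  unbalanced ratios, a correlated genomic-like stand-in, permutation nulls;
* `subsample_class_pmf()`, `prob_unequal_composition()`,
  `preference_fraction()` — the analytic imbalance theory and its
  diagnostics;
* `run_bias_study()`, `run_preference_study()`, `tune_mtry()`,
  `procedure2_error()`, `run_tuning_bias_study()`,
  `run_tuning_consequence_study()` — seeded Monte-Carlo drivers for the
  bias grids and the consequences for `mtry` tuning.

See the vignette (`vignettes/oob-error-bias.Rmd`) for the model, the
parameter conventions and all numerical choices.

## Worked example

One repetition of the high-risk setting — balanced binary null case,
n = 20, p = 1000, where the true error rate of any classifier is 0.5:

```r
library(oobias)
set.seed(1)
design <- simulation_design(20, 1000)   # balanced binary null: true error 0.5
train  <- generate_dataset(design)
test   <- generate_test_set(design, realize_effects(design), 2000)

f_unstrat <- subforest(train, mtry = 31, ntree = 500)
f_strat   <- subforest(train, mtry = 31, ntree = 500, scheme = "stratified")

oob_error(f_unstrat)
#> OOB error: 0.6000  (mtry = 31, ntree = 500, 20 evaluable)
#>   class-specific: 0.6000, 0.6000
oob_error(f_strat)
#> STRAT_OOB error: 0.3500  (mtry = 31, ntree = 500, 20 evaluable)
#>   class-specific: 0.4000, 0.3000
test_error(f_unstrat, test)
#> TEST error: 0.5055  (mtry = 31, ntree = 500, 2000 evaluable)
#>   class-specific: 0.4620, 0.5490
```

The unstratified OOB error (0.60) overshoots the true error; the test error
on 2000 fresh observations sits at chance (0.5055); the stratified OOB
error is a single-repetition draw around chance (0.35 here — individual
repetitions are noisy with n = 20; `run_bias_study()` averages them). The
driving distribution is available in closed form:

```r
subsample_class_pmf(10, 10, 12)
#> Class-1 count in a subsample of 12 from (10, 10): hypergeometric
#>       2       3       4       5       6       7       8       9      10
#> 0.00036 0.00953 0.07502 0.24006 0.35008 0.24006 0.07502 0.00953 0.00036
prob_unequal_composition(10, 10, 12)
#> [1] 0.6499166
```

Even with perfectly balanced training data, 65% of the per-tree subsamples
are unbalanced — the source of the pessimism above.

Averaged studies are one call, e.g. the bias grid of the setting above:

```r
res <- run_bias_study(simulation_design(20, 1000), reps = 50, ntree = 500,
                      test_size = 2000, estimators = c("TEST", "OOB", "STRAT_OOB"),
                      seed = 101)
summarize_study(res)
```

which reports mean test errors of ~0.50 at every mtry, mean OOB errors of
0.61–0.75 (largest at mtry = 1), and mean stratified OOB errors within 0.03
of the test error.

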