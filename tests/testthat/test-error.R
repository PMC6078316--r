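test_that("a constant majority-class predictor errs at the minority share", {
  set.seed(1)
  train <- null_dataset(20, 4, props = c(0.3, 0.7))
  f <- constant_forest(train, class = 2)
  test <- null_dataset(1000, 4, props = c(0.3, 0.7))
  rep <- test_error(f, test)
  expect_equal(rep$overall_error, 0.3)
  expect_equal(rep$per_class_error, c(1, 0))
  expect_equal(rep$n_evaluable, 1000)
  # the same constant forest's OOB error matches the training minority share
  oob <- oob_error(f)
  expect_equal(oob$overall_error,
               mean(train$labels[oob_votes(f)$evaluable] == 1))
})

test_that("overall error is the class-count-weighted mean of class errors", {
  set.seed(2)
  for (i in 1:5) {
    ds <- generate_dataset(simulation_design(40, 6, n_effect = 2,
                                             effect_mean_loc = 0.75,
                                             class_proportions = c(0.6, 0.4)))
    f <- subforest(ds, mtry = 2, ntree = 50)
    for (rep in list(oob_error(f),
                     test_error(f, null_dataset(200, 6)))) {
      w <- rep$n_per_class / rep$n_evaluable
      expect_equal(rep$overall_error,
                   sum(w * rep$per_class_error))
      expect_true(all(rep$per_class_error >= 0 &
                        rep$per_class_error <= 1))
      expect_equal(class_specific_errors(rep), rep$per_class_error)
    }
  }
})

test_that("fold assignments partition the data evenly", {
  set.seed(3)
  labels <- rep(1:2, each = 10)
  fold <- make_folds(labels, 10)
  expect_equal(sort(unique(fold)), 1:10)
  expect_true(all(tabulate(fold, 10) == 2))
  # stratified balanced: exactly one per class per fold
  sfold <- make_folds(labels, 10, stratified = TRUE)
  for (f in 1:10) {
    expect_equal(tabulate(labels[sfold == f], 2), c(1, 1))
  }
  # stratified unbalanced (9, 21): class counts within apportionment bounds
  labs <- rep(1:2, c(9, 21))
  expect_warning(sf <- make_folds(labs, 10, stratified = TRUE), "miss")
  per_fold <- t(vapply(1:10, function(f) tabulate(labs[sf == f], 2),
                       numeric(2)))
  expect_true(all(per_fold[, 1] %in% 0:1))
  expect_true(all(per_fold[, 2] %in% 2:3))
  expect_true(all(abs(rowSums(per_fold) - 3) <= 1))
  expect_error(make_folds(labels, 1), "folds")
  expect_warning(make_folds(rep(1:2, c(3, 17)), 10, stratified = TRUE),
                 "miss")
})

test_that("cross-validation is exact on separable data and averages folds", {
  set.seed(4)
  x <- matrix(rnorm(40 * 3), 40, 3)
  y <- ifelse(x[, 1] > 0, 2L, 1L)
  x[, 1] <- x[, 1] + ifelse(y == 2, 3, -3)  # wide margin
  ds <- labeled_dataset(x, y)
  rep <- cv_error(ds, mtry = 3, ntree = 30, l = 5)
  expect_equal(rep$overall_error, 0)
  expect_length(rep$fold_errors, 5)
  expect_equal(rep$estimator, "CV")
  # the reported error is the unweighted fold mean
  set.seed(5)
  ds2 <- null_dataset(21, 4, props = c(8, 13) / 21)
  rep2 <- cv_error(ds2, mtry = 2, ntree = 30, l = 2)
  expect_equal(rep2$overall_error, mean(rep2$fold_errors))
  # stratified folds tag the estimator
  expect_equal(cv_error(ds2, 2, 20, l = 3, stratified = TRUE)$estimator,
               "STRAT_CV")
})

test_that("a fold that strips a class from the training split is refused", {
  set.seed(6)
  ds <- null_dataset(12, 3, props = c(10, 2) / 12)
  folds <- integer(12)
  folds[ds$labels == 2] <- 1L          # both minority rows in fold 1
  folds[ds$labels == 1] <- rep_len(2:4, 10)
  attr(folds, "stratified") <- FALSE
  expect_error(cv_error(ds, 1, 10, folds = folds), "fold 1")
})

test_that("balanced sampling equalizes class-specific errors on 1:5 data", {
  set.seed(7)
  design <- simulation_design(60, 50, class_proportions = c(5, 1) / 6,
                              n_effect = 10, effect_mean_loc = 0.75)
  gaps_bal <- gaps_prop <- numeric(5)
  for (r in 1:5) {
    eff <- realize_effects(design)
    train <- generate_dataset(design, eff)
    test <- generate_test_set(design, eff, 600)
    bal <- test_error(subforest(train, mtry = 7, ntree = 300,
                                scheme = "balanced"), test)
    prop <- test_error(subforest(train, mtry = 7, ntree = 300,
                                 scheme = "stratified"), test)
    gaps_bal[r] <- diff(bal$per_class_error)
    gaps_prop[r] <- diff(prop$per_class_error)
  }
  # equal-number sampling makes the two class-specific test errors close,
  # while class-proportional sampling leaves the minority class far worse
  expect_lt(abs(mean(gaps_bal)), 0.15)
  expect_gt(mean(gaps_prop), 0.3)
})

test_that("reports serialize to JSON and long-format rows", {
  set.seed(8)
  ds <- null_dataset(20, 4)
  f <- subforest(ds, mtry = 2, ntree = 20)
  rep <- oob_error(f)
  row <- as.data.frame(rep)
  expect_equal(row$overall_error, rep$overall_error)
  expect_named(row, c("estimator", "scheme", "mtry", "ntree",
                      "overall_error", "n_evaluable", "err_class_1",
                      "err_class_2"))
  path <- withr::local_tempfile(fileext = ".json")
  write_error_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$overall_error, rep$overall_error)
  expect_equal(back$estimator, "OOB")
})
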