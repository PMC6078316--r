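test_that("bias studies produce one complete row per requested cell", {
  res <- run_bias_study(simulation_design(16, 6), mtry_grid = c(1L, 3L, 6L),
                        reps = 3, ntree = 20, test_size = 60,
                        estimators = c("TEST", "OOB", "STRAT_OOB"),
                        seed = 42)
  expect_s3_class(res, "study_result")
  expect_equal(nrow(res), 3 * 3 * 3)
  expect_true(all(res$status == "ok"))
  expect_equal(sort(unique(res$mtry)), c(1, 3, 6))
  with_tab <- table(res$estimator, res$mtry)
  expect_true(all(with_tab == 3))
  # every estimator of a repetition sees the same realized training data
  fp <- tapply(res$data_fp, res$rep, function(v) length(unique(v)))
  expect_true(all(fp == 1))
  expect_true(all(res$overall_error >= 0 & res$overall_error <= 1))
})

test_that("study replays are byte-identical under one master seed", {
  cfg <- function() {
    run_bias_study(simulation_design(14, 5), mtry_grid = c(1L, 5L),
                   reps = 2, ntree = 15, test_size = 40,
                   estimators = c("TEST", "OOB", "CV", "STRAT_CV"),
                   seed = 7, cv_folds = 5)
  }
  expect_identical(cfg(), cfg())
})

test_that("summaries match independent recomputation", {
  set.seed(1)
  res <- run_bias_study(simulation_design(16, 6), mtry_grid = c(2L, 6L),
                        reps = 4, ntree = 15, test_size = 40,
                        estimators = c("TEST", "OOB"), seed = 3)
  sm <- summarize_study(res)
  expect_equal(nrow(sm), 4)
  for (i in seq_len(nrow(sm))) {
    v <- res$overall_error[res$estimator == sm$estimator[i] &
                             res$mtry == sm$mtry[i]]
    expect_equal(sm$mean_error[i], sum(v) / length(v))
    expect_equal(sm$mc_se[i],
                 sqrt(sum((v - mean(v))^2) / (length(v) - 1)) /
                   sqrt(length(v)))
    expect_equal(sm$n_reps[i], 4L)
  }
  # single-row groups have zero standard error
  one <- summarize_study(res[res$rep == 1, ])
  expect_true(all(one$mc_se == 0))
})

test_that("mtry tuning picks the grid minimum and echoes the search", {
  set.seed(2)
  ds <- generate_dataset(simulation_design(24, 8, n_effect = 3,
                                           effect_mean_loc = 1.5))
  tuned <- tune_mtry(ds, grid = c(1L, 4L, 8L), ntree = 40)
  expect_s3_class(tuned, "mtry_tuning")
  expect_true(tuned$chosen_mtry %in% c(1, 4, 8))
  expect_equal(tuned$error_p1, min(tuned$oob_errors))
  expect_equal(unname(which.min(tuned$oob_errors)),
               match(tuned$chosen_mtry, c(1, 4, 8)))
  # degenerate grid of one value
  t1 <- tune_mtry(ds, grid = 4L, ntree = 20)
  expect_equal(t1$chosen_mtry, 4L)
  expect_equal(t1$error_p1, unname(t1$oob_errors[1]))
  # procedure 2 re-estimates at the chosen mtry on a fresh forest
  p2 <- procedure2_error(ds, tuned$chosen_mtry, ntree = 40)
  expect_true(p2 >= 0 && p2 <= 1)
})

test_that("tuning studies report every repetition and scheme", {
  res <- run_tuning_bias_study(simulation_design(16, 6, n_effect = 3,
                                                 effect_mean_loc = 1),
                               grid = c(1L, 6L), reps = 3, ntree = 15,
                               test_size = 40, seed = 9)
  expect_equal(nrow(res), 3 * 2)
  expect_setequal(unique(res$scheme), c("unstratified", "stratified"))
  expect_true(all(res$chosen_mtry %in% c(1, 6)))
  expect_true(all(res$error_p1 >= 0 & res$error_p1 <= 1))
  expect_true(all(res$test_error >= 0 & res$test_error <= 1))
  cons <- run_tuning_consequence_study(
    simulation_design(16, 6, n_effect = 3, effect_mean_loc = 1),
    grid = c(1L, 6L), reps = 2, ntree = 15, test_size = 40,
    cv_folds = 4, seed = 9)
  expect_equal(nrow(cons), 2 * 4)
  expect_equal(as.vector(table(cons$selector)), rep(2L, 4))
  expect_true(all(cons$chosen_mtry %in% c(1, 6)))
})

test_that("study results round-trip to CSV deterministically", {
  res <- run_bias_study(simulation_design(14, 5), mtry_grid = c(1L, 5L),
                        reps = 2, ntree = 10, test_size = 30,
                        estimators = "OOB", seed = 11)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_study_csv(res, p1)
  write_study_csv(res, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- utils::read.csv(p1)
  expect_equal(back$overall_error, res$overall_error)
})
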