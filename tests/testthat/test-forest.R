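test_that("in-bag sets match the scheme and OOB sets are their complement", {
  set.seed(1)
  ds <- null_dataset(20, 5)
  f <- subforest(ds, mtry = 2, ntree = 30)
  expect_length(f$inbag, 30)
  for (ib in f$inbag) {
    expect_length(ib, 12)
    expect_false(anyDuplicated(ib) > 0)
  }
  ov <- oob_votes(f)
  # each row is OOB for exactly the trees that exclude it
  expected_oob <- vapply(1:20, function(i) {
    sum(!vapply(f$inbag, function(ib) i %in% ib, logical(1)))
  }, numeric(1))
  expect_equal(ov$n_oob_trees, as.integer(expected_oob))
  expect_equal(rowSums(ov$counts), expected_oob)
  # stratified scheme on balanced n=20: exactly 6 per class in every bag
  fs <- subforest(ds, mtry = 2, ntree = 20, scheme = "stratified")
  for (ib in fs$inbag) {
    expect_equal(tabulate(ds$labels[ib], 2), c(6, 6))
  }
})

test_that("per-tree votes agree with the tree learner's own predictions", {
  set.seed(2)
  ds <- generate_dataset(simulation_design(40, 12, n_effect = 4,
                                           effect_mean_loc = 1))
  for (mt in c(1, 4, 12)) {
    f <- subforest(ds, mtry = mt, ntree = 25)
    xt <- matrix(rnorm(100 * 12), 100, 12)
    colnames(xt) <- colnames(ds$features)
    mine <- predict(f, xt, type = "votes")
    theirs <- predict(f$fit, xt, predict.all = TRUE,
                      num.threads = 1)$predictions
    expect_equal(unname(mine), unname(theirs))
  }
})

test_that("pure in-bag samples give single-leaf constant trees", {
  set.seed(3)
  ds <- null_dataset(20, 4)
  f <- constant_forest(ds, class = 2, ntree = 5)
  xt <- matrix(rnorm(50 * 4), 50, 4)
  expect_true(all(predict(f, xt, type = "votes") == 2))
  expect_true(all(predict(f, xt) == 2))
})

test_that("fully grown trees reproduce their in-bag labels at mtry = p", {
  set.seed(4)
  x <- matrix(rnorm(30 * 3), 30, 3)
  y <- ifelse(x[, 1] > 0, 2L, 1L)
  y[1:2] <- c(1L, 2L)  # ensure both classes even if x1 signs collapse
  ds <- labeled_dataset(x, y)
  f <- subforest(ds, mtry = 3, ntree = 20)
  votes <- predict(f, ds, type = "votes")
  for (t in seq_len(f$ntree)) {
    ib <- f$inbag[[t]]
    expect_equal(votes[ib, t], ds$labels[ib])
  }
})

test_that("the candidate-restriction contract responds to mtry", {
  # with strong signal on x1, root splits almost always use x1 when all
  # predictors are candidates, and rarely when only one random candidate
  # is drawn per split
  set.seed(5)
  p <- 25
  x <- matrix(rnorm(60 * p), 60, p)
  y <- ifelse(x[, 1] + 0.2 * rnorm(60) > 0, 2L, 1L)
  y[1:2] <- c(1L, 2L)
  ds <- labeled_dataset(x, y)
  root_x1 <- function(mtry) {
    f <- subforest(ds, mtry = mtry, ntree = 60)
    mean(vapply(seq_len(60), function(t) {
      ranger::treeInfo(f$fit, t)$splitvarName[1] == "x1"
    }, logical(1)))
  }
  expect_gt(root_x1(p), 0.9)
  expect_lt(root_x1(1), 0.3)
})

test_that("forest vote ties break towards the smallest class label", {
  set.seed(6)
  ds <- null_dataset(8, 3)
  # two constant trees voting for different classes -> tie -> class 1
  inbag <- list(which(ds$labels == 1), which(ds$labels == 2))
  f <- subforest(ds, mtry = 1, ntree = 2, inbag = inbag)
  xt <- matrix(rnorm(20 * 3), 20, 3)
  votes <- predict(f, xt, type = "votes")
  expect_true(all(sort(unique(as.vector(votes))) == 1:2))
  expect_true(all(predict(f, xt) == 1))
})

test_that("a one-tree forest predicts like its tree and marks in-bag rows", {
  set.seed(7)
  ds <- null_dataset(16, 4)
  f <- subforest(ds, mtry = 2, ntree = 1)
  votes <- predict(f, ds, type = "votes")
  expect_equal(predict(f, ds), as.vector(votes))
  ov <- oob_votes(f)
  expect_equal(which(!ov$evaluable), f$inbag[[1]])
})

test_that("refitting under the same seed replays the forest exactly", {
  ds <- null_dataset(20, 6)
  fit_once <- function() {
    set.seed(123)
    f <- subforest(ds, mtry = 2, ntree = 25)
    list(inbag = f$inbag, pred = predict(f, ds, type = "votes"),
         oob = oob_error(f)$overall_error)
  }
  expect_identical(fit_once(), fit_once())
})

test_that("preference fraction is the predicted share of the target class", {
  set.seed(8)
  ds <- null_dataset(12, 3)
  f <- constant_forest(ds, class = 2)
  xt <- matrix(rnorm(40 * 3), 40, 3)
  expect_equal(preference_fraction(f, xt, 2), 1)
  expect_equal(preference_fraction(f, xt, 1), 0)
})

test_that("forest interfaces agree and serialize", {
  set.seed(9)
  ds <- null_dataset(20, 4)
  df <- as.data.frame(ds)
  set.seed(11); f1 <- subforest(ds, mtry = 2, ntree = 10)
  set.seed(11); f2 <- subforest(class ~ ., df, mtry = 2, ntree = 10)
  xt <- matrix(rnorm(30 * 4), 30, 4)
  expect_equal(predict(f1, xt), predict(f2, xt))
  expect_error(predict(f1, xt[, 1:3]), "predictors")
  expect_error(subforest(ds, mtry = 9), "mtry")
  path <- withr::local_tempfile(fileext = ".json")
  write_forest_manifest(f1, path)
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_equal(man$mtry, 2)
  inbag_back <- lapply(man$inbag, function(v) as.integer(unlist(v)))
  expect_equal(inbag_back[[3]], f1$inbag[[3]])
  # replaying the manifest's in-bag sets reproduces the OOB bookkeeping
  f3 <- subforest(ds, mtry = 2, ntree = 10, inbag = inbag_back)
  expect_equal(oob_votes(f3)$n_oob_trees, oob_votes(f1)$n_oob_trees)
})
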