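#' Monte-Carlo bias-quantification study
#'
#' Runs the core experiment of the package: for each repetition a fresh
#' effect profile, training set and independent test set are realized from a
#' \code{\link{simulation_design}}, and for every mtry value on the grid the
#' requested error estimators are computed \emph{on the same data}, so the
#' estimators are compared pairwise within repetitions. The test and OOB
#' errors come from a forest with unstratified subsampling, the stratified
#' OOB error from a forest with class-proportional stratified subsampling,
#' and the (stratified) CV errors from 10-fold cross-validation with
#' (stratified) folds.
#'
#' Estimator tags: \code{"TEST"}, \code{"OOB"}, \code{"STRAT_OOB"},
#' \code{"CV"}, \code{"STRAT_CV"}.
#'
#' @param design a \code{\link{simulation_design}}.
#' @param mtry_grid increasing mtry values in \code{1..p}; defaults to the
#'   study grid for \code{design$p}.
#' @param reps repetitions (full-scale studies use 500).
#' @param ntree trees per forest (full-scale studies use 1000).
#' @param test_size independent test observations per repetition
#'   (full-scale studies use 10000).
#' @param estimators subset of the five estimator tags.
#' @param seed master seed; per-repetition streams come from
#'   \code{\link{rep_seeds}}.
#' @param cv_folds folds for the CV estimators.
#' @return A long-format data frame of class \code{"study_result"}: one row
#'   per (repetition, mtry, estimator) with the overall and class-specific
#'   errors, the repetition seed, a fingerprint of the realized training
#'   features (identical across estimators within a repetition), and a
#'   \code{status} column (\code{"ok"} or the failure message of that cell).
#' @examples
#' \donttest{
#' res <- run_bias_study(simulation_design(20, 10), reps = 3, ntree = 50,
#'                       test_size = 200, seed = 1)
#' summarize_study(res)
#' }
#' @export
run_bias_study <- function(design, mtry_grid = default_mtry_grid(design$p),
                           reps = 100, ntree = 500, test_size = 2000,
                           estimators = c("TEST", "OOB", "STRAT_OOB"),
                           seed = 1, cv_folds = 10) {
  stopifnot(inherits(design, "simulation_design"))
  estimators <- match.arg(estimators,
                          c("TEST", "OOB", "STRAT_OOB", "CV", "STRAT_CV"),
                          several.ok = TRUE)
  if (any(mtry_grid < 1 | mtry_grid > design$p) ||
      is.unsorted(mtry_grid, strictly = TRUE)) {
    stop("mtry_grid must be strictly increasing within 1..p")
  }
  setting <- sprintf("n%d_p%d_k%d_%s", design$n, design$p, design$k,
                     if (design$n_effect > 0) "power" else "null")
  seeds <- rep_seeds(seed, reps)
  rows <- list()
  blank <- rep(NA_real_, design$k)

  emit <- function(rep_i, mtry, estimator, scheme, res, fp) {
    if (inherits(res, "error_report")) {
      overall <- res$overall_error
      per_class <- res$per_class_error
      n_eval <- res$n_evaluable
      status <- "ok"
    } else {
      overall <- NA_real_; per_class <- blank; n_eval <- NA_integer_
      status <- conditionMessage(res)
    }
    row <- data.frame(setting_id = setting, estimator = estimator,
                      scheme = scheme, mtry = mtry, ntree = ntree,
                      rep = rep_i, seed = seeds[rep_i], data_fp = fp,
                      overall_error = overall, n_evaluable = n_eval,
                      status = status)
    pc <- as.data.frame(as.list(per_class))
    names(pc) <- paste0("err_class_", seq_len(design$k))
    rows[[length(rows) + 1L]] <<- cbind(row, pc)
  }
  try_cell <- function(expr) tryCatch(expr, error = function(e) e)

  for (r in seq_len(reps)) {
    set.seed(seeds[r])
    effects <- realize_effects(design)
    train <- generate_dataset(design, effects)
    test <- if ("TEST" %in% estimators) {
      generate_test_set(design, effects, test_size)
    }
    fp <- signif(sum(train$features), 12)
    for (mt in mtry_grid) {
      if (any(c("TEST", "OOB") %in% estimators)) {
        f_u <- try_cell(subforest(train, mtry = mt, ntree = ntree,
                                  scheme = "unstratified"))
        if ("TEST" %in% estimators) {
          emit(r, mt, "TEST", "unstratified",
               try_cell(test_error(f_u, test)), fp)
        }
        if ("OOB" %in% estimators) {
          emit(r, mt, "OOB", "unstratified", try_cell(oob_error(f_u)), fp)
        }
      }
      if ("STRAT_OOB" %in% estimators) {
        emit(r, mt, "STRAT_OOB", "stratified",
             try_cell(oob_error(subforest(train, mtry = mt, ntree = ntree,
                                          scheme = "stratified"))), fp)
      }
      if ("CV" %in% estimators) {
        emit(r, mt, "CV", "unstratified",
             try_cell(cv_error(train, mt, ntree, "unstratified",
                               l = cv_folds, stratified = FALSE)), fp)
      }
      if ("STRAT_CV" %in% estimators) {
        emit(r, mt, "STRAT_CV", "unstratified",
             try_cell(cv_error(train, mt, ntree, "unstratified",
                               l = cv_folds, stratified = TRUE)), fp)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("study_result", "data.frame")
  res
}

#' Summarize a study result
#'
#' Grouped means and Monte-Carlo standard errors of the overall error over
#' repetitions, per estimator and mtry value. Failed cells are dropped.
#'
#' @param result a \code{"study_result"} data frame.
#' @return data frame with columns \code{estimator}, \code{mtry},
#'   \code{mean_error}, \code{mc_se}, \code{n_reps}.
#' @export
summarize_study <- function(result) {
  stopifnot(is.data.frame(result), nrow(result) > 0)
  ok <- result[result$status == "ok", ]
  if (nrow(ok) == 0) stop("no successful cells to summarize")
  agg <- aggregate(overall_error ~ estimator + mtry, data = ok,
                   FUN = function(v) c(mean = mean(v),
                                       se = if (length(v) > 1) {
                                         sd(v) / sqrt(length(v))
                                       } else 0,
                                       n = length(v)))
  out <- data.frame(estimator = agg$estimator, mtry = agg$mtry,
                    mean_error = agg$overall_error[, "mean"],
                    mc_se = agg$overall_error[, "se"],
                    n_reps = as.integer(agg$overall_error[, "n"]))
  out[order(out$estimator, out$mtry), , drop = FALSE]
}

#' Write a study result to CSV
#'
#' Plain long-format CSV; identical configurations and master seeds produce
#' byte-identical files.
#'
#' @param result a \code{"study_result"} (or any) data frame.
#' @param path output file.
#' @export
write_study_csv <- function(result, path) {
  write.csv(result, path, row.names = FALSE)
  invisible(path)
}

#' Select mtry by the smallest OOB error
#'
#' Builds one forest per grid value and selects the mtry with the smallest
#' OOB error; ties are broken towards the smallest mtry. The minimum itself
#' is the "procedure (1)" error estimate — the same OOB errors are used both
#' to pick mtry and to report the error, which makes it optimistically
#' biased.
#'
#' @param ds training \code{\link{labeled_dataset}}.
#' @param grid increasing mtry values.
#' @param ntree trees per forest.
#' @param scheme sampling scheme for the tuning forests.
#' @return An object of class \code{"mtry_tuning"}: list with
#'   \code{chosen_mtry}, \code{error_p1} (the minimum OOB error) and
#'   \code{oob_errors} (named by mtry).
#' @export
tune_mtry <- function(ds, grid = default_mtry_grid(ncol(ds$features)),
                      ntree = 500, scheme = sampling_scheme("unstratified")) {
  stopifnot(inherits(ds, "labeled_dataset"))
  errs <- vapply(grid, function(mt) {
    oob_error(subforest(ds, mtry = mt, ntree = ntree,
                        scheme = scheme))$overall_error
  }, numeric(1))
  names(errs) <- grid
  best <- which.min(errs)  # first minimum = smallest mtry on ties
  structure(list(chosen_mtry = as.integer(grid[best]),
                 error_p1 = unname(errs[best]), oob_errors = errs,
                 scheme = as_scheme(scheme)$kind),
            class = "mtry_tuning")
}

#' @export
print.mtry_tuning <- function(x, ...) {
  cat(sprintf("mtry tuning (%s sampling): chosen mtry = %d, ",
              x$scheme, x$chosen_mtry))
  cat(sprintf("minimum OOB error (procedure 1) = %.4f\n", x$error_p1))
  invisible(x)
}

#' "Procedure (2)" error estimate at a tuned mtry
#'
#' Builds a fresh, independently seeded forest at the previously chosen mtry
#' and reports its OOB error. Because the new forest's subsamples are drawn
#' anew, the estimate avoids most of the selection optimism of taking the
#' minimum OOB error over the grid.
#'
#' @param ds training \code{\link{labeled_dataset}}.
#' @param chosen_mtry mtry selected by \code{\link{tune_mtry}}.
#' @param ntree,scheme forest settings.
#' @return the OOB error (a number).
#' @export
procedure2_error <- function(ds, chosen_mtry, ntree = 500,
                             scheme = sampling_scheme("unstratified")) {
  oob_error(subforest(ds, mtry = chosen_mtry, ntree = ntree,
                      scheme = scheme))$overall_error
}

#' Optimism of tuning-plus-reporting procedures
#'
#' Per repetition and sampling scheme: tune mtry over the grid by OOB error
#' (procedure 1 = report the minimum), rebuild a fresh forest at the chosen
#' mtry (procedure 2 = report its OOB error), and evaluate the fresh forest
#' on an independent test set. Over repetitions, procedure 1's mean is at or
#' below procedure 2's, and with stratified sampling procedure 2 tracks the
#' test error closely.
#'
#' @param design a \code{\link{simulation_design}} (a power case with many
#'   effect predictors is where the biases are largest).
#' @param grid mtry grid for the tuning search.
#' @param reps,ntree,test_size study scale.
#' @param schemes sampling schemes to compare.
#' @param seed master seed.
#' @return data frame with one row per (rep, scheme): \code{chosen_mtry},
#'   \code{error_p1}, \code{error_p2}, \code{test_error}.
#' @export
run_tuning_bias_study <- function(design,
                                  grid = default_mtry_grid(design$p),
                                  reps = 50, ntree = 500, test_size = 2000,
                                  schemes = c("unstratified", "stratified"),
                                  seed = 1) {
  stopifnot(inherits(design, "simulation_design"))
  seeds <- rep_seeds(seed, reps)
  rows <- list()
  for (r in seq_len(reps)) {
    set.seed(seeds[r])
    effects <- realize_effects(design)
    train <- generate_dataset(design, effects)
    test <- generate_test_set(design, effects, test_size)
    for (sc in schemes) {
      tuned <- tune_mtry(train, grid, ntree, sc)
      final <- subforest(train, mtry = tuned$chosen_mtry, ntree = ntree,
                         scheme = sc)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, scheme = sc, chosen_mtry = tuned$chosen_mtry,
        error_p1 = tuned$error_p1,
        error_p2 = oob_error(final)$overall_error,
        test_error = test_error(final, test)$overall_error)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Consequences of estimator choice for mtry selection
#'
#' Per repetition: mtry is selected by each of four estimators — OOB,
#' stratified OOB, CV, stratified CV — and the resulting classifier
#' (unstratified sampling for the unstratified selectors, stratified
#' sampling for the stratified ones) is evaluated on an independent test
#' set. Comparable mean test errors across selectors indicate that the OOB
#' bias has little consequence for tuning.
#'
#' @param design a \code{\link{simulation_design}}.
#' @param grid mtry grid for the tuning search.
#' @param reps,ntree,test_size study scale.
#' @param selectors subset of \code{c("OOB", "STRAT_OOB", "CV",
#'   "STRAT_CV")}.
#' @param cv_folds folds for the CV selectors.
#' @param seed master seed.
#' @return data frame with one row per (rep, selector): \code{chosen_mtry}
#'   and \code{test_error}.
#' @export
run_tuning_consequence_study <- function(design,
                                         grid = default_mtry_grid(design$p),
                                         reps = 50, ntree = 500,
                                         test_size = 2000,
                                         selectors = c("OOB", "STRAT_OOB",
                                                       "CV", "STRAT_CV"),
                                         cv_folds = 10, seed = 1) {
  stopifnot(inherits(design, "simulation_design"))
  selectors <- match.arg(selectors, c("OOB", "STRAT_OOB", "CV", "STRAT_CV"),
                         several.ok = TRUE)
  seeds <- rep_seeds(seed, reps)
  rows <- list()
  for (r in seq_len(reps)) {
    set.seed(seeds[r])
    effects <- realize_effects(design)
    train <- generate_dataset(design, effects)
    test <- generate_test_set(design, effects, test_size)
    for (sel in selectors) {
      final_scheme <- if (sel %in% c("STRAT_OOB", "STRAT_CV")) {
        "stratified"
      } else {
        "unstratified"
      }
      errs <- switch(sel,
        OOB = tune_mtry(train, grid, ntree, "unstratified")$oob_errors,
        STRAT_OOB = tune_mtry(train, grid, ntree, "stratified")$oob_errors,
        CV = vapply(grid, function(mt) {
          cv_error(train, mt, ntree, "unstratified", l = cv_folds,
                   stratified = FALSE)$overall_error
        }, numeric(1)),
        STRAT_CV = vapply(grid, function(mt) {
          cv_error(train, mt, ntree, "unstratified", l = cv_folds,
                   stratified = TRUE)$overall_error
        }, numeric(1)))
      chosen <- grid[which.min(errs)]
      final <- subforest(train, mtry = chosen, ntree = ntree,
                         scheme = final_scheme)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, selector = sel, chosen_mtry = as.integer(chosen),
        test_error = test_error(final, test)$overall_error)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
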