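# Build an error report from truth/prediction pairs. `pred` may contain NA
# for non-evaluable observations (e.g. rows never out-of-bag).
error_report <- function(truth, pred, k, estimator,
                         mtry = NA_integer_, ntree = NA_integer_,
                         scheme = NA_character_, fold_errors = NULL) {
  ok <- !is.na(pred)
  if (!any(ok)) stop("no evaluable observations")
  per_class <- vapply(seq_len(k), function(cl) {
    rows <- ok & truth == cl
    if (any(rows)) mean(pred[rows] != cl) else NA_real_
  }, numeric(1))
  n_class <- vapply(seq_len(k), function(cl) sum(ok & truth == cl),
                    integer(1))
  overall <- if (is.null(fold_errors)) {
    mean(pred[ok] != truth[ok])
  } else {
    mean(fold_errors)  # unweighted fold mean, the CV aggregation rule
  }
  structure(list(overall_error = overall, per_class_error = per_class,
                 n_per_class = n_class, n_evaluable = sum(ok),
                 estimator = estimator, mtry = mtry, ntree = ntree,
                 scheme = scheme, fold_errors = fold_errors),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("%s error: %.4f  (mtry = %s, ntree = %s, %d evaluable)\n",
              x$estimator, x$overall_error,
              ifelse(is.na(x$mtry), "-", x$mtry),
              ifelse(is.na(x$ntree), "-", x$ntree), x$n_evaluable))
  cat("  class-specific:",
      paste(sprintf("%.4f", x$per_class_error), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.error_report <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  row <- data.frame(estimator = x$estimator,
                    scheme = x$scheme, mtry = x$mtry, ntree = x$ntree,
                    overall_error = x$overall_error,
                    n_evaluable = x$n_evaluable)
  pc <- as.data.frame(as.list(x$per_class_error))
  names(pc) <- paste0("err_class_", seq_along(x$per_class_error))
  cbind(row, pc)
}

#' Serialize an error report to JSON
#'
#' @param x an error report as returned by \code{\link{test_error}},
#'   \code{\link{oob_error}} or \code{\link{cv_error}}.
#' @param path output file.
#' @export
write_error_report <- function(x, path) {
  stopifnot(inherits(x, "error_report"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Class-specific error rates of a report
#'
#' Entry \code{j} is the misclassification rate restricted to evaluable
#' observations whose true class is \code{j} (NA if a class has none). The
#' class-count-weighted mean of these entries equals the overall error
#' exactly (for fold-averaged CV reports the identity holds for the pooled
#' error, not the unweighted fold mean).
#'
#' @param x an \code{error_report}.
#' @return numeric vector of length k.
#' @export
class_specific_errors <- function(x) {
  stopifnot(inherits(x, "error_report"))
  x$per_class_error
}

#' Independent test-set error
#'
#' Misclassification rate of forest majority-vote predictions on data not
#' used in any way for construction — the gold standard the OOB and CV
#' estimators are compared against.
#'
#' @param object a \code{\link{subforest}}.
#' @param test a \code{\link{labeled_dataset}}, disjoint from the training
#'   data (the caller's responsibility).
#' @return an \code{error_report} (estimator tag \code{"TEST"}).
#' @export
test_error <- function(object, test) {
  stopifnot(inherits(object, "subforest"), inherits(test, "labeled_dataset"))
  if (nrow(test$features) == 0) stop("empty test set")
  pred <- predict(object, test)
  error_report(test$labels, pred, object$k, "TEST",
               object$mtry, object$ntree, object$scheme$kind)
}

#' Out-of-bag error
#'
#' For each training row, the majority vote over exactly those trees for
#' which the row was out-of-bag is compared with the true label; the error is
#' aggregated over evaluable rows. Computed on a forest built with the
#' \code{"stratified"} scheme this is the stratified OOB error (tag
#' \code{"STRAT_OOB"}); on other schemes the tag is \code{"OOB"}.
#'
#' @param object a \code{\link{subforest}}.
#' @return an \code{error_report}.
#' @export
oob_error <- function(object) {
  stopifnot(inherits(object, "subforest"))
  ov <- oob_votes(object)
  pred <- majority_from_counts(ov$counts, object$tie_break)
  pred[!ov$evaluable] <- NA_integer_
  tag <- if (object$scheme$kind == "stratified") "STRAT_OOB" else "OOB"
  error_report(object$training$labels, pred, object$k, tag,
               object$mtry, object$ntree, object$scheme$kind)
}

#' Cross-validation fold assignment
#'
#' Partitions \code{1..n} into \code{l} folds whose sizes differ by at most
#' one. With \code{stratified = TRUE}, rows are dealt round-robin within
#' class (after shuffling), so within-fold class counts also differ by at
#' most one across folds and each fold's class distribution matches the data
#' as closely as integers allow.
#'
#' @param labels integer class labels.
#' @param l number of folds (default 10).
#' @param stratified preserve the class distribution within folds?
#' @param k number of classes.
#' @return integer vector of fold indices in \code{1..l}, with attribute
#'   \code{"stratified"}.
#' @export
make_folds <- function(labels, l = 10, stratified = FALSE, k = max(labels)) {
  n <- length(labels)
  if (l < 2) stop("need at least 2 folds")
  if (l > n) stop("more folds than observations")
  fold <- integer(n)
  if (stratified) {
    if (min(tabulate(labels, k)) < l) {
      warning("a class is smaller than the number of folds; ",
              "some folds will miss it")
    }
    ord <- unlist(lapply(seq_len(k), function(cl) {
      rows <- which(labels == cl)
      rows[sample.int(length(rows))]
    }))
  } else {
    ord <- sample.int(n)
  }
  fold[ord] <- rep_len(seq_len(l), n)
  attr(fold, "stratified") <- stratified
  fold
}

#' Cross-validation error of a subsampling forest
#'
#' \code{l}-fold CV: for each fold, a forest is fitted on the remaining rows
#' (under the given sampling scheme) and the misclassification rate on the
#' held-out fold is computed. The reported overall error is the
#' \emph{unweighted} mean of the \code{l} fold error rates; class-specific
#' errors are pooled over folds for stability. With stratified folds the
#' estimator tag is \code{"STRAT_CV"}, otherwise \code{"CV"}.
#'
#' @param ds training \code{\link{labeled_dataset}}.
#' @param mtry,ntree,scheme forest settings, as in \code{\link{subforest}}.
#' @param folds a fold assignment from \code{\link{make_folds}}; built
#'   fresh (with \code{l}, \code{stratified}) when omitted.
#' @param l,stratified fold construction when \code{folds} is missing.
#' @return an \code{error_report} with a \code{fold_errors} component.
#' @export
cv_error <- function(ds, mtry, ntree = 500,
                     scheme = sampling_scheme("unstratified"),
                     folds = NULL, l = 10, stratified = FALSE) {
  stopifnot(inherits(ds, "labeled_dataset"))
  scheme <- as_scheme(scheme)
  if (is.null(folds)) {
    folds <- make_folds(ds$labels, l, stratified, ds$k)
  }
  nf <- max(folds)
  pred <- integer(length(ds$labels))
  fold_err <- numeric(nf)
  for (f in seq_len(nf)) {
    hold <- which(folds == f)
    keep <- which(folds != f)
    present <- tabulate(ds$labels[keep], ds$k)
    if (any(present == 0)) {
      stop("fold ", f, " leaves the training split without class ",
           which(present == 0)[1])
    }
    forest <- subforest(ds$features[keep, , drop = FALSE], ds$labels[keep],
                        mtry = mtry, ntree = ntree, scheme = scheme)
    pred[hold] <- predict(forest, ds$features[hold, , drop = FALSE])
    fold_err[f] <- mean(pred[hold] != ds$labels[hold])
  }
  tag <- if (isTRUE(attr(folds, "stratified"))) "STRAT_CV" else "CV"
  error_report(ds$labels, pred, ds$k, tag, mtry, ntree, scheme$kind,
               fold_errors = fold_err)
}
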