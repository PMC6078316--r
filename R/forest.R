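#' Subsampling random forest with explicit in-bag bookkeeping
#'
#' Fits an ensemble of fully grown CART-style classification trees, each on a
#' without-replacement subsample of the training rows drawn under a
#' \code{\link{sampling_scheme}}. At every split of every tree, \code{mtry}
#' candidate predictors are drawn uniformly without replacement and the best
#' Gini-impurity-decreasing axis-aligned split among them is taken; trees are
#' grown until nodes are pure or unsplittable. The per-tree in-bag index sets
#' are retained verbatim, so all out-of-bag (OOB) quantities are exactly
#' reproducible from the fitted object.
#'
#' Tree induction is delegated to \pkg{ranger} with per-tree in-bag sets
#' supplied by this package; subsample drawing, OOB bookkeeping and vote
#' aggregation (including the deterministic tie rule) are implemented here.
#' All randomness is taken from R's global RNG stream, so results are
#' reproducible with \code{set.seed}.
#'
#' @param x training features: a numeric matrix, a data frame, or a
#'   \code{\link{labeled_dataset}} (in which case \code{y} is taken from it).
#'   A formula interface \code{subforest(class ~ ., data)} is also available.
#' @param y class labels (integer or factor), ignored when \code{x} is a
#'   \code{labeled_dataset}.
#' @param mtry number of candidate predictors per split, in \code{1..p}.
#' @param ntree number of trees (the full-scale studies use 1000).
#' @param scheme a \code{\link{sampling_scheme}} or kind string.
#' @param inbag optional list of \code{ntree} integer index vectors to use as
#'   in-bag sets instead of drawing them (for replay and for degenerate
#'   fixtures); sizes are not re-prescribed by the scheme in that case.
#' @param tie_break how forest majority votes break exact ties:
#'   \code{"smallest"} (deterministic, default) predicts the smallest class
#'   label, \code{"random"} picks uniformly among the tied classes.
#' @param ... passed between methods.
#' @return An object of class \code{"subforest"}: a list with the fitted
#'   \pkg{ranger} ensemble (\code{fit}), the in-bag index sets
#'   (\code{inbag}), the training data (\code{training}), and the settings
#'   \code{mtry}, \code{ntree}, \code{scheme}, \code{k}, \code{n_train},
#'   \code{class_labels}, \code{tie_break}.
#' @examples
#' set.seed(1)
#' ds <- generate_dataset(simulation_design(20, 10))
#' f <- subforest(ds, mtry = 3, ntree = 50)
#' f
#' oob_error(f)
#' @export
subforest <- function(x, ...) UseMethod("subforest")

#' @rdname subforest
#' @param formula model formula; the response is the class label.
#' @param data data frame holding the formula variables.
#' @export
subforest.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- mf[-1]
  subforest.default(x, y, ...)
}

#' @rdname subforest
#' @export
subforest.labeled_dataset <- function(x, ...) {
  subforest.default(x$features, x$labels, ...)
}

#' @rdname subforest
#' @export
subforest.default <- function(x, y, mtry = floor(sqrt(ncol(x))), ntree = 500,
                              scheme = sampling_scheme("unstratified"),
                              inbag = NULL,
                              tie_break = c("smallest", "random"), ...) {
  tie_break <- match.arg(tie_break)
  scheme <- as_scheme(scheme)
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  class_labels <- if (is.factor(y)) levels(y) else as.character(sort(unique(y)))
  labels <- if (is.factor(y)) as.integer(y) else match(y, sort(unique(y)))
  k <- length(class_labels)
  n <- nrow(x)
  p <- ncol(x)
  if (length(labels) != n) stop("x and y sizes disagree")
  if (mtry < 1 || mtry > p) stop("mtry must lie in 1..p = ", p)
  if (ntree < 1) stop("ntree must be >= 1")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))

  if (is.null(inbag)) {
    inbag <- replicate(ntree, draw_subsample(labels, scheme, k),
                       simplify = FALSE)
  } else {
    if (length(inbag) != ntree) stop("inbag must hold one index set per tree")
    inbag <- lapply(inbag, function(i) sort(as.integer(i)))
  }
  counts <- lapply(inbag, function(idx) {
    cnt <- integer(n)
    cnt[idx] <- 1L
    cnt
  })
  # tree induction is seeded from the R stream for end-to-end reproducibility
  ranger_seed <- sample.int(.Machine$integer.max, 1)
  fit <- ranger::ranger(x = x, y = factor(labels, levels = seq_len(k),
                                          labels = class_labels),
                        num.trees = ntree, mtry = mtry, replace = FALSE,
                        inbag = counts, min.node.size = 1,
                        num.threads = 1, seed = ranger_seed,
                        verbose = FALSE)
  structure(list(fit = fit, inbag = inbag,
                 training = structure(list(features = x, labels = labels,
                                           k = as.integer(k)),
                                      class = "labeled_dataset"),
                 mtry = as.integer(mtry), ntree = as.integer(ntree),
                 scheme = scheme, k = as.integer(k), n_train = as.integer(n),
                 class_labels = class_labels, tie_break = tie_break,
                 ranger_seed = ranger_seed),
            class = "subforest")
}

#' @export
print.subforest <- function(x, ...) {
  cat(sprintf("Subsampling forest: %d trees, mtry = %d, p = %d\n",
              x$ntree, x$mtry, ncol(x$training$features)))
  cat(sprintf("  training: n = %d, %d classes (%s)\n", x$n_train, x$k,
              paste(class_counts(x$training), collapse = "/")))
  cat("  sampling:", x$scheme$kind, "without replacement, in-bag size",
      length(x$inbag[[1]]), "\n")
  invisible(x)
}

#' @export
summary.subforest <- function(object, ...) {
  print(object)
  rep <- oob_error(object)
  cat(sprintf("  OOB error: %.4f (%d evaluable observations)\n",
              rep$overall_error, rep$n_evaluable))
  invisible(rep)
}

# Feature matrix out of whatever the caller supplies.
as_feature_matrix <- function(newdata) {
  if (inherits(newdata, "labeled_dataset")) return(newdata$features)
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  newdata
}

# n x ntree matrix of per-tree class predictions (1-based codes), by direct
# traversal of the stored tree arrays.
tree_votes <- function(object, newdata) {
  x <- as_feature_matrix(newdata)
  if (ncol(x) != ncol(object$training$features)) {
    stop("newdata has ", ncol(x), " predictors; the forest was trained on ",
         ncol(object$training$features))
  }
  fr <- object$fit$forest
  tree_votes_cpp(x,
                 lapply(fr$child.nodeIDs, function(ch) as.integer(ch[[1]])),
                 lapply(fr$child.nodeIDs, function(ch) as.integer(ch[[2]])),
                 lapply(fr$split.varIDs, as.integer),
                 fr$split.values)
}

# Majority vote over a class-count matrix, honoring the forest's tie rule.
majority_from_counts <- function(counts, tie_break) {
  if (tie_break == "smallest") {
    return(max.col(counts, ties.method = "first"))
  }
  max.col(counts, ties.method = "random")
}

#' Predict classes with a subsampling forest
#'
#' Majority vote over all trees; exact vote ties are broken by the forest's
#' tie rule (deterministically towards the smallest class label by default).
#'
#' @param object a \code{\link{subforest}}.
#' @param newdata feature matrix, data frame or \code{labeled_dataset}.
#' @param type \code{"response"} for predicted class indices (1..k),
#'   \code{"counts"} for the n x k matrix of tree votes, or \code{"votes"}
#'   for the raw n x ntree per-tree prediction matrix.
#' @param ... ignored.
#' @return integer vector or matrix, see \code{type}.
#' @export
predict.subforest <- function(object, newdata,
                              type = c("response", "counts", "votes"), ...) {
  type <- match.arg(type)
  votes <- tree_votes(object, newdata)
  if (type == "votes") return(votes)
  counts <- oob_vote_counts_cpp(votes,
                                matrix(TRUE, nrow(votes), ncol(votes)),
                                object$k)
  colnames(counts) <- object$class_labels
  if (type == "counts") return(counts)
  majority_from_counts(counts, object$tie_break)
}

#' Out-of-bag votes and evaluability
#'
#' For every training row, counts the class votes of exactly those trees
#' whose in-bag set excludes the row. Rows that are in-bag for all trees
#' carry no OOB information and are flagged non-evaluable (with
#' \code{ntree >= 100} this is vanishingly rare).
#'
#' @param object a \code{\link{subforest}}.
#' @return list with \code{counts} (n x k vote-count matrix),
#'   \code{n_oob_trees} (trees for which each row is OOB) and
#'   \code{evaluable} (logical).
#' @export
oob_votes <- function(object) {
  stopifnot(inherits(object, "subforest"))
  votes <- tree_votes(object, object$training)
  oob <- matrix(TRUE, object$n_train, object$ntree)
  for (t in seq_len(object$ntree)) oob[object$inbag[[t]], t] <- FALSE
  counts <- oob_vote_counts_cpp(votes, oob, object$k)
  colnames(counts) <- object$class_labels
  n_oob <- as.integer(rowSums(oob))
  list(counts = counts, n_oob_trees = n_oob, evaluable = n_oob > 0L)
}

#' Fraction of predictions assigned to a class
#'
#' The class-preference diagnostic: the proportion of observations in
#' \code{newdata} that the forest classifies as \code{target_class}. Applied
#' to balanced null-case test data it measures how strongly the trees favor
#' the majority class of an unbalanced training sample.
#'
#' @param object a \code{\link{subforest}}.
#' @param newdata feature matrix, data frame or \code{labeled_dataset}.
#' @param target_class class index in 1..k.
#' @return a number in \code{[0, 1]}.
#' @export
preference_fraction <- function(object, newdata, target_class) {
  stopifnot(target_class >= 1, target_class <= object$k)
  mean(predict(object, newdata) == target_class)
}

#' Serialize the sampling record of a forest to JSON
#'
#' Writes everything needed to re-derive all OOB quantities: the scheme,
#' mtry, ntree, the tree-induction seed and the per-tree in-bag index sets.
#' Tree internals are not included (refit with the same seed and in-bag sets
#' reproduces them).
#'
#' @param object a \code{\link{subforest}}.
#' @param path output file.
#' @export
write_forest_manifest <- function(object, path) {
  stopifnot(inherits(object, "subforest"))
  jsonlite::write_json(
    list(scheme = unclass(object$scheme), mtry = object$mtry,
         ntree = object$ntree, n_train = object$n_train, k = object$k,
         class_labels = object$class_labels,
         ranger_seed = object$ranger_seed, inbag = object$inbag),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
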