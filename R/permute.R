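#' Permutation null: break predictor-response association
#'
#' Randomly permutes the labels while leaving the feature matrix untouched.
#' All associations between predictors and the response are destroyed, but
#' the correlation structure among predictors and the class counts are
#' preserved exactly.
#'
#' @param ds a \code{\link{labeled_dataset}}.
#' @return a \code{\link{labeled_dataset}} with permuted labels.
#' @export
permute_response <- function(ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  ds$labels <- ds$labels[sample.int(length(ds$labels))]
  ds
}

#' Permutation null: break inter-predictor correlation
#'
#' Permutes each predictor column independently with its own random
#' permutation. This creates (approximate) independence between predictors
#' and also breaks any predictor-response association, while preserving each
#' column's marginal distribution exactly. Labels are unchanged.
#'
#' @param ds a \code{\link{labeled_dataset}}.
#' @return a \code{\link{labeled_dataset}}.
#' @export
permute_each_predictor <- function(ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  n <- nrow(ds$features)
  for (j in seq_len(ncol(ds$features))) {
    ds$features[, j] <- ds$features[sample.int(n), j]
  }
  ds
}

#' Correlated genomic-like null data
#'
#' Generates a feature matrix with block-exchangeable correlation: predictors
#' are partitioned into consecutive blocks of \code{block_size} columns with
#' pairwise correlation \code{rho} within a block and independence across
#' blocks. Labels are assigned by \code{class_props} independently of the
#' features, so the result is a null case by construction. This is a synthetic
#' stand-in for high-dimensional expression matrices, where genes come in
#' correlated groups; it is not fitted to any particular real data set.
#'
#' The construction uses the one-factor representation of an exchangeable
#' Gaussian block: \code{x = sqrt(rho) * z_block + sqrt(1 - rho) * e}.
#'
#' @param n observations, \code{p} predictors.
#' @param p number of predictors.
#' @param block_size size of each correlated block (last block may be
#'   shorter); \code{block_size = 1} gives independent columns.
#' @param rho within-block correlation, \code{0 <= rho < 1}.
#' @param class_props class proportions (largest-remainder counts).
#' @return a \code{\link{labeled_dataset}}.
#' @export
generate_correlated_dataset <- function(n, p, block_size, rho,
                                        class_props = c(0.5, 0.5)) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  stopifnot(block_size >= 1, p >= 1, n >= length(class_props))
  x <- matrix(rnorm(n * p), n, p) * sqrt(1 - rho)
  if (rho > 0 && block_size > 1) {
    nblock <- ceiling(p / block_size)
    z <- matrix(rnorm(n * nblock), n, nblock)
    block_of <- rep(seq_len(nblock), each = block_size)[seq_len(p)]
    x <- x + sqrt(rho) * z[, block_of, drop = FALSE]
  } else if (rho > 0) {
    # block_size 1: no shared factor, restore unit marginal variance
    x <- x / sqrt(1 - rho)
  }
  counts <- largest_remainder(n, class_props)
  labeled_dataset(x, rep.int(seq_along(counts), counts),
                  k = length(class_props))
}

#' Draw a training subset with a per-class minimum
#'
#' Draws a simple random subset of \code{n_train} observations by rejection
#' sampling, accepting only draws in which every class contributes at least
#' \code{min_per_class} observations (the real-data style draw uses a minimum
#' of 8 per class). The complement is returned as the evaluation remainder.
#'
#' @param ds a \code{\link{labeled_dataset}}.
#' @param n_train training subset size.
#' @param min_per_class minimum observations per class (0 disables the
#'   constraint and yields a plain simple random subset).
#' @param max_tries rejection-sampling cap before giving up.
#' @return list with elements \code{train} and \code{remainder}, both
#'   \code{\link{labeled_dataset}}s (the remainder may be empty).
#' @export
draw_training_subset <- function(ds, n_train, min_per_class = 0,
                                 max_tries = 10000) {
  stopifnot(inherits(ds, "labeled_dataset"))
  n <- nrow(ds$features)
  if (n_train > n) stop("n_train exceeds the number of observations")
  if (min_per_class * ds$k > n_train) {
    stop("infeasible: min_per_class * k = ", min_per_class * ds$k,
         " exceeds n_train = ", n_train)
  }
  if (any(class_counts(ds) < min_per_class)) {
    stop("a class has fewer than min_per_class observations")
  }
  for (i in seq_len(max_tries)) {
    idx <- sort(sample.int(n, n_train))
    if (min_per_class == 0 ||
        all(tabulate(ds$labels[idx], ds$k) >= min_per_class)) {
      return(list(train = subset_rows(ds, idx),
                  remainder = subset_rows(ds, setdiff(seq_len(n), idx))))
    }
  }
  stop("no subset satisfying the per-class minimum found in ", max_tries,
       " draws")
}

#' Largest remainder subset matching the training class distribution
#'
#' From the remainder of a training/test split, extracts the largest subset
#' whose class-count vector is an exact integer multiple of the training
#' class ratio (in lowest terms), so that the test set has the same response
#' class distribution as the training set. Observations are sampled without
#' replacement within each class.
#'
#' @param remainder a \code{\link{labeled_dataset}}.
#' @param train_class_counts integer vector of training class counts.
#' @return a \code{\link{labeled_dataset}}; empty (with a warning) if no
#'   positive multiple of the ratio fits in the remainder.
#' @export
match_test_distribution <- function(remainder, train_class_counts) {
  stopifnot(inherits(remainder, "labeled_dataset"))
  if (length(train_class_counts) != remainder$k) {
    stop("train_class_counts must have length k")
  }
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  ratio <- as.integer(train_class_counts)
  ratio <- ratio %/% Reduce(gcd2, ratio)
  avail <- class_counts(remainder)
  s <- min(avail %/% ratio)
  if (s < 1) {
    warning("remainder holds no positive multiple of the training class ",
            "ratio; returning an empty subset")
    return(subset_rows(remainder, integer(0)))
  }
  idx <- unlist(lapply(seq_len(remainder$k), function(cl) {
    rows <- which(remainder$labels == cl)
    rows[sample.int(length(rows), s * ratio[cl])]
  }))
  subset_rows(remainder, sort(idx))
}
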