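#' Hypergeometric distribution of subsample class composition
#'
#' When a without-replacement subsample of size \code{m} is drawn from
#' \code{n1} class-1 and \code{n2} class-2 observations, the number of
#' class-1 observations in the subsample is hypergeometric:
#' \deqn{P(X = x) = \frac{\binom{n_1}{x}\binom{n_2}{m-x}}{\binom{n_1+n_2}{m}}}
#' over the support \code{max(0, m - n2) .. min(m, n1)}. The spread of this
#' distribution is the driver of the OOB pessimism: for small \code{n} the
#' subsamples of a balanced sample are frequently unbalanced, and the trees
#' grown on them preferentially predict their in-bag majority class.
#'
#' @param n1,n2 class sizes in the original sample.
#' @param m subsample size (the subsampling forest uses
#'   \code{floor(0.632 * (n1 + n2))}).
#' @return An object of class \code{"imbalance_pmf"}: list with
#'   \code{n1}, \code{n2}, \code{m}, \code{support} and \code{pmf}.
#' @examples
#' d <- subsample_class_pmf(10, 10, 12)
#' sum(d$pmf)                   # 1
#' sum(d$support * d$pmf)       # m * n1 / (n1 + n2) = 6
#' @export
subsample_class_pmf <- function(n1, n2, m) {
  if (n1 < 0 || n2 < 0 || m < 0) stop("n1, n2 and m must be non-negative")
  if (m > n1 + n2) stop("m cannot exceed n1 + n2")
  support <- max(0, m - n2):min(m, n1)
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), m = as.integer(m),
                 support = as.integer(support),
                 pmf = dhyper(support, n1, n2, m)),
            class = "imbalance_pmf")
}

#' @export
print.imbalance_pmf <- function(x, ...) {
  cat(sprintf(
    "Class-1 count in a subsample of %d from (%d, %d): hypergeometric\n",
    x$m, x$n1, x$n2))
  print(stats::setNames(round(x$pmf, 5), x$support))
  invisible(x)
}

#' Serialize a composition pmf to JSON
#'
#' @param x an \code{\link{subsample_class_pmf}} result.
#' @param path output file.
#' @export
write_pmf_json <- function(x, path) {
  stopifnot(inherits(x, "imbalance_pmf"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Probability of an unequal-composition subsample
#'
#' The probability that a without-replacement subsample of size \code{m}
#' contains different numbers of class-1 and class-2 observations. For odd
#' \code{m} equality is impossible and the probability is exactly 1; for
#' even \code{m} it is \code{1 - P(X = m/2)} under the hypergeometric law of
#' \code{\link{subsample_class_pmf}}.
#'
#' @param n1,n2,m as in \code{\link{subsample_class_pmf}}.
#' @return a probability.
#' @export
prob_unequal_composition <- function(n1, n2, m) {
  if (m %% 2 == 1) return(1)
  d <- subsample_class_pmf(n1, n2, m)
  half <- m %/% 2
  p_eq <- if (half %in% d$support) d$pmf[match(half, d$support)] else 0
  1 - p_eq
}

#' Monte-Carlo composition frequencies of a sampling scheme
#'
#' Draws repeated in-bag samples with \code{\link{draw_subsample}} and
#' tabulates the class-1 count, for validating the analytic pmf
#' (unstratified draws) or demonstrating that stratification removes the
#' composition variability entirely (point mass).
#'
#' @param labels integer class labels of the sample.
#' @param scheme a \code{\link{sampling_scheme}} or kind string.
#' @param m_reps number of Monte-Carlo draws.
#' @return data frame with columns \code{count} and \code{freq} (relative
#'   frequencies over the draws).
#' @export
empirical_composition <- function(labels, scheme, m_reps) {
  stopifnot(m_reps >= 1)
  scheme <- as_scheme(scheme)
  k <- max(labels)
  counts <- vapply(seq_len(m_reps), function(i) {
    sum(labels[draw_subsample(labels, scheme, k)] == 1L)
  }, integer(1))
  tab <- table(counts)
  data.frame(count = as.integer(names(tab)),
             freq = as.numeric(tab) / m_reps)
}

#' Class-preference study on unbalanced null training data
#'
#' Reproduces the preference mechanism study: forests are trained on
#' null-case data with \code{n1} minority and \code{n2} majority
#' observations (all predictors i.i.d. N(0,1)), and the fraction of
#' minority-class predictions on a balanced test set is recorded per mtry
#' value. Small mtry and large p drive the fraction towards zero — the trees
#' almost always predict the majority class.
#'
#' @param p_values predictor counts to study (the published setup uses
#'   10, 100, 1000).
#' @param n1,n2 minority and majority training class sizes (10 and 20).
#' @param n_test balanced test-set size (the full-scale study uses 10000).
#' @param reps repetitions per (p, mtry) cell.
#' @param ntree trees per forest.
#' @param mtry_grids optional named list (by p) of mtry grids; defaults to
#'   \code{\link{default_mtry_grid}}.
#' @param seed master seed for the per-repetition streams.
#' @return data frame with columns \code{p}, \code{mtry}, \code{rep},
#'   \code{minority_fraction}.
#' @export
run_preference_study <- function(p_values = c(10, 100, 1000), n1 = 10,
                                 n2 = 20, n_test = 2000, reps = 100,
                                 ntree = 500, mtry_grids = NULL, seed = 1) {
  seeds <- rep_seeds(seed, reps)
  out <- vector("list", length(p_values))
  for (pi in seq_along(p_values)) {
    p <- p_values[pi]
    grid <- if (!is.null(mtry_grids)) {
      mtry_grids[[as.character(p)]]
    } else {
      default_mtry_grid(p)
    }
    design <- simulation_design(n1 + n2, p,
                                class_proportions = c(n1, n2) / (n1 + n2))
    cells <- vector("list", reps)
    for (r in seq_len(reps)) {
      set.seed(seeds[r])
      train <- generate_dataset(design)
      test_x <- matrix(rnorm(n_test * p), n_test, p)
      frac <- vapply(grid, function(mt) {
        f <- subforest(train, mtry = mt, ntree = ntree,
                       scheme = "unstratified")
        preference_fraction(f, test_x, target_class = 1L)
      }, numeric(1))
      cells[[r]] <- data.frame(p = p, mtry = grid, rep = r,
                               minority_fraction = frac)
    }
    out[[pi]] <- do.call(rbind, cells)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
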