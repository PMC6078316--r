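#' Simulation design for null- and power-case class data
#'
#' Describes one simulated data setting: \code{n} training observations on
#' \code{p} i.i.d. Gaussian predictors split into \code{k} classes with fixed
#' class proportions. In a power case the first \code{n_effect} predictors
#' carry class-dependent means: for each repetition, the mean of effect
#' predictor \code{j} in class \code{r >= 2} is drawn afresh from
#' \code{N(effect_mean_loc, effect_mean_scale^2)} (class 1 is always the
#' \code{N(0,1)} reference). \code{n_effect = 0} encodes a null case. The
#' hyperparameter locations used in the studies are 0.75 (binary, p in
#' \{10, 100\}), 0.1 (binary, p = 1000) and 0.4 (four classes).
#'
#' @param n training sample size.
#' @param p number of predictors.
#' @param k number of classes (the studies use 2 or 4).
#' @param class_proportions length-\code{k} vector of positive fractions
#'   summing to 1; defaults to balanced.
#' @param n_effect number of predictors with class-dependent means (0..p).
#' @param effect_mean_loc location of the Gaussian from which per-class,
#'   per-predictor effect means are drawn.
#' @param effect_mean_scale its standard deviation (1 in all study designs).
#' @return An object of class \code{"simulation_design"}.
#' @examples
#' # binary balanced null case, n = 20, p = 1000
#' simulation_design(20, 1000)
#' # binary unbalanced power case (30% minority), p = 100, 10 effects
#' simulation_design(30, 100, class_proportions = c(0.7, 0.3),
#'                   n_effect = 10, effect_mean_loc = 0.75)
#' @export
simulation_design <- function(n, p, k = 2,
                              class_proportions = rep(1 / k, k),
                              n_effect = 0, effect_mean_loc = 0,
                              effect_mean_scale = 1) {
  stopifnot(n >= k, p >= 1, k >= 2)
  if (length(class_proportions) != k) {
    stop("class_proportions must have length k = ", k)
  }
  if (any(class_proportions <= 0)) {
    stop("class_proportions must be strictly positive")
  }
  if (abs(sum(class_proportions) - 1) > 1e-12) {
    stop("class_proportions must sum to 1")
  }
  if (n_effect < 0 || n_effect > p) stop("n_effect must lie in 0..p")
  structure(list(n = as.integer(n), p = as.integer(p), k = as.integer(k),
                 class_proportions = as.numeric(class_proportions),
                 n_effect = as.integer(n_effect),
                 effect_mean_loc = effect_mean_loc,
                 effect_mean_scale = effect_mean_scale),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf("Simulation design: n=%d, p=%d, k=%d (%s case)\n",
              x$n, x$p, x$k, if (x$n_effect > 0) "power" else "null"))
  cat("  class proportions:", paste(signif(x$class_proportions, 4),
                                    collapse = ":"), "\n")
  if (x$n_effect > 0) {
    cat(sprintf("  %d effect predictors, means ~ N(%g, %g^2)\n",
                x$n_effect, x$effect_mean_loc, x$effect_mean_scale))
  }
  invisible(x)
}

#' Realize the class-conditional effect means of one repetition
#'
#' Draws the matrix of class-conditional means for the effect predictors.
#' Row 1 (the reference class) is identically zero; entries of rows
#' \code{2..k} are i.i.d. \code{N(effect_mean_loc, effect_mean_scale^2)}.
#' A fresh profile is drawn for every repetition of a study so that effect
#' strengths vary across repetitions; the same profile must be shared by the
#' training and test set of a repetition.
#'
#' @param design a \code{\link{simulation_design}}.
#' @return a \code{k x n_effect} numeric matrix (zero columns for a null
#'   design).
#' @export
realize_effects <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  means <- matrix(0, design$k, design$n_effect)
  if (design$n_effect > 0 && design$k > 1) {
    means[-1, ] <- rnorm((design$k - 1) * design$n_effect,
                         design$effect_mean_loc, design$effect_mean_scale)
  }
  means
}

# Shared generator: per-class counts by largest remainder, features Gaussian
# with the realized class-conditional means on the effect columns.
generate_gaussian <- function(design, effects, n_obs) {
  if (n_obs < design$k) {
    stop("n_obs must be at least the number of classes (", design$k, ")")
  }
  counts <- largest_remainder(n_obs, design$class_proportions)
  labels <- rep.int(seq_len(design$k), counts)
  x <- matrix(rnorm(n_obs * design$p), n_obs, design$p)
  if (design$n_effect > 0) {
    for (r in seq_len(design$k)[-1]) {
      rows <- which(labels == r)
      if (length(rows)) {
        x[rows, seq_len(design$n_effect)] <-
          x[rows, seq_len(design$n_effect), drop = FALSE] +
          rep(effects[r, ], each = length(rows))
      }
    }
  }
  labeled_dataset(x, labels, k = design$k)
}

#' Generate a training dataset from a simulation design
#'
#' Draws exactly \code{round(n_obs * class_proportions[r])} observations of
#' each class \code{r} (largest-remainder rounding, so counts sum to
#' \code{n_obs}). Features of a class-\code{r} observation are independent
#' Gaussians with unit variance: effect predictor \code{j} has mean
#' \code{effects[r, j]}, all other predictors mean 0.
#'
#' @param design a \code{\link{simulation_design}}.
#' @param effects effect-mean matrix from \code{\link{realize_effects}}.
#' @param n_obs number of observations (defaults to \code{design$n}).
#' @return a \code{\link{labeled_dataset}}.
#' @examples
#' d <- simulation_design(20, 10)
#' set.seed(1)
#' ds <- generate_dataset(d, realize_effects(d))
#' class_counts(ds)  # 10 10
#' @export
generate_dataset <- function(design, effects = realize_effects(design),
                             n_obs = design$n) {
  stopifnot(inherits(design, "simulation_design"))
  generate_gaussian(design, effects, n_obs)
}

#' Generate an independent test set of the same repetition
#'
#' Test observations follow the same distribution as the training data of the
#' repetition: the same realized effect profile and the same class
#' proportions.
#'
#' @param design a \code{\link{simulation_design}}.
#' @param effects the effect profile realized for the repetition's training
#'   set.
#' @param m number of test observations (the full-scale studies use 10000).
#' @return a \code{\link{labeled_dataset}}.
#' @export
generate_test_set <- function(design, effects, m) {
  stopifnot(inherits(design, "simulation_design"))
  if (m < design$k) stop("test size m must be at least k")
  generate_gaussian(design, effects, m)
}
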