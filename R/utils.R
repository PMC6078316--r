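# Largest-remainder apportionment of `total` items to fractional shares.
# Guarantees counts sum exactly to `total` and deviate from exact
# proportionality by less than 1. Remainder ties go to the earliest share.
largest_remainder <- function(total, shares) {
  shares <- shares / sum(shares)
  exact <- total * shares
  counts <- floor(exact)
  short <- as.integer(round(total - sum(counts)))
  if (short > 0L) {
    take <- order(exact - counts, decreasing = TRUE)[seq_len(short)]
    counts[take] <- counts[take] + 1L
  }
  as.integer(counts)
}

#' Independently seeded repetition streams
#'
#' Spawns one RNG seed per repetition from a master seed, drawn in documented
#' order (a single \code{sample.int} call on the master-seeded stream), so
#' repetitions are reproducible independently of execution order.
#'
#' @param master_seed integer master seed.
#' @param reps number of repetitions.
#' @return integer vector of \code{reps} seeds.
#' @export
rep_seeds <- function(master_seed, reps) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max, reps)
}

#' mtry grids used throughout the simulation studies
#'
#' Returns the grid of candidate-predictor counts matched to the number of
#' predictors: \code{1..10} for \code{p = 10}, \code{1, 10, 20, ..., 100} for
#' \code{p = 100} and \code{1, 5, 10, 50, 100, 200, 300, ..., 1000} for
#' \code{p = 1000}. For other \code{p} a log-spaced grid
#' \code{1, 10, 100, 500, 1000, 2000, ..., p} is used, as in the
#' high-dimensional real-data settings.
#'
#' @param p number of predictors.
#' @return increasing integer vector of mtry values, all in \code{[1, p]}.
#' @export
default_mtry_grid <- function(p) {
  g <- if (p == 10) {
    1:10
  } else if (p == 100) {
    c(1L, seq(10L, 100L, 10L))
  } else if (p == 1000) {
    c(1L, 5L, 10L, 50L, 100L, seq(200L, 1000L, 100L))
  } else {
    sort(unique(c(1L, 10L, 100L, 500L,
                  seq(1000L, max(1000L, p), 1000L), as.integer(p))))
  }
  as.integer(g[g <= p])
}
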