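#' Per-tree subsampling scheme
#'
#' Defines how the in-bag sample of each tree is drawn from the training
#' rows. Sampling is always without replacement. Three rules are supported:
#' \describe{
#'   \item{\code{"unstratified"}}{a uniform random subset of
#'     \code{floor(subsample_fraction * n)} rows (the classical subsampling
#'     forest; fraction 0.632).}
#'   \item{\code{"stratified"}}{the same total size, apportioned to classes
#'     proportionally to their sizes (largest-remainder rule) and drawn
#'     uniformly within each class, so the class distribution of the training
#'     data is preserved in every subsample.}
#'   \item{\code{"balanced"}}{exactly \code{floor(balanced_fraction *
#'     n_small)} rows from every class, where \code{n_small} is the smallest
#'     class size (the balanced forest variant; fraction 0.75).}
#' }
#'
#' @param kind one of \code{"unstratified"}, \code{"stratified"},
#'   \code{"balanced"}.
#' @param subsample_fraction in-bag fraction of \code{n} for the first two
#'   kinds; default 0.632.
#' @param balanced_fraction per-class fraction of the smallest class size for
#'   the balanced kind; default 0.75.
#' @return An object of class \code{"sampling_scheme"}.
#' @examples
#' sampling_scheme("stratified")
#' @export
sampling_scheme <- function(kind = c("unstratified", "stratified", "balanced"),
                            subsample_fraction = 0.632,
                            balanced_fraction = 0.75) {
  kind <- match.arg(kind)
  if (subsample_fraction <= 0 || subsample_fraction > 1 ||
      balanced_fraction <= 0 || balanced_fraction > 1) {
    stop("sampling fractions must lie in (0, 1]")
  }
  structure(list(kind = kind, subsample_fraction = subsample_fraction,
                 balanced_fraction = balanced_fraction),
            class = "sampling_scheme")
}

#' @export
print.sampling_scheme <- function(x, ...) {
  frac <- if (x$kind == "balanced") {
    paste0(x$balanced_fraction, " * n_small per class")
  } else {
    paste0("floor(", x$subsample_fraction, " * n) total")
  }
  cat("Sampling scheme:", x$kind, "without replacement,", frac, "\n")
  invisible(x)
}

as_scheme <- function(scheme) {
  if (inherits(scheme, "sampling_scheme")) scheme else sampling_scheme(scheme)
}

# Prescribed per-class in-bag counts for a label vector under a scheme.
scheme_class_counts <- function(labels, k, scheme) {
  sizes <- tabulate(labels, k)
  switch(scheme$kind,
    unstratified = NULL,  # no per-class prescription
    stratified = largest_remainder(floor(scheme$subsample_fraction *
                                           length(labels)), sizes),
    balanced = rep.int(as.integer(floor(scheme$balanced_fraction *
                                          min(sizes))), k))
}

#' Draw one in-bag index set
#'
#' Draws the without-replacement in-bag sample of a single tree according to
#' a \code{\link{sampling_scheme}}.
#'
#' @param labels integer class labels of the training rows (1..k).
#' @param scheme a \code{\link{sampling_scheme}} or a kind string.
#' @param k number of classes (defaults to \code{max(labels)}).
#' @return sorted integer vector of in-bag row indices.
#' @examples
#' set.seed(1)
#' length(draw_subsample(rep(1:2, each = 10), "unstratified"))  # floor(.632*20)
#' @export
draw_subsample <- function(labels, scheme, k = max(labels)) {
  scheme <- as_scheme(scheme)
  n <- length(labels)
  if (n < 2) stop("need at least 2 observations")
  sizes <- tabulate(labels, k)
  if (any(sizes == 0)) stop("every class must be non-empty")
  if (scheme$kind == "unstratified") {
    return(sort(sample.int(n, floor(scheme$subsample_fraction * n))))
  }
  per_class <- scheme_class_counts(labels, k, scheme)
  if (any(per_class > sizes)) {
    stop("a class is smaller than its prescribed in-bag draw")
  }
  idx <- unlist(lapply(seq_len(k), function(cl) {
    rows <- which(labels == cl)
    rows[sample.int(length(rows), per_class[cl])]
  }))
  sort(idx)
}
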