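#' Labeled dataset of metric predictors
#'
#' The universal container of every stage of the package: a numeric feature
#' matrix of \code{n} observations by \code{p} metric predictors together with
#' integer class labels in \code{1..k}. Every class must be represented at
#' least once and features must be complete (no missing values).
#'
#' @param features numeric matrix, observations in rows.
#' @param labels integer (or factor) vector of class labels in \code{1..k};
#'   a factor is converted via its level index.
#' @param k number of classes; defaults to \code{max(labels)}.
#' @return An object of class \code{"labeled_dataset"}: a list with elements
#'   \code{features}, \code{labels} (integer) and \code{k}.
#' @examples
#' ds <- labeled_dataset(matrix(rnorm(40), 20, 2), rep(1:2, each = 10))
#' table(ds$labels)
#' @export
labeled_dataset <- function(features, labels, k = NULL) {
  if (!is.matrix(features)) features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.factor(labels)) labels <- as.integer(labels)
  labels <- as.integer(labels)
  if (is.null(k)) k <- max(labels)
  if (nrow(features) != length(labels)) {
    stop("labels length (", length(labels), ") does not match feature rows (",
         nrow(features), ")")
  }
  if (anyNA(features)) stop("features contain missing values")
  if (any(labels < 1L | labels > k)) stop("labels must lie in 1..k")
  if (!all(seq_len(k) %in% labels)) {
    stop("every class in 1..", k, " must have at least one observation")
  }
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  }
  structure(list(features = features, labels = labels, k = as.integer(k)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled dataset: ", nrow(x$features), " observations, ",
      ncol(x$features), " metric predictors, ", x$k, " classes\n", sep = "")
  cat("Class counts:", paste(class_counts(x), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.labeled_dataset <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(x$features, class = x$labels)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$features)

#' Per-class observation counts
#'
#' @param ds a \code{\link{labeled_dataset}}.
#' @return integer vector of length \code{ds$k}.
#' @export
class_counts <- function(ds) {
  tabulate(ds$labels, nbins = ds$k)
}

# Row subset, preserving k even if a class drops out of the subset.
subset_rows <- function(ds, idx) {
  structure(list(features = ds$features[idx, , drop = FALSE],
                 labels = ds$labels[idx], k = ds$k),
            class = "labeled_dataset")
}

#' Read a labeled dataset from a delimited text file
#'
#' Reads a plain CSV/TSV table (header row) with one designated label column;
#' all remaining columns must parse as numbers. The delimiter is chosen from
#' the file extension (\code{.tsv}/\code{.txt} use tab, otherwise comma).
#'
#' @param path file path.
#' @param label name of the label column (default \code{"class"}).
#' @param k number of classes, defaulting to the largest label.
#' @return a \code{\link{labeled_dataset}}.
#' @export
read_labeled_dataset <- function(path, label = "class", k = NULL) {
  tab <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    read.delim(path, check.names = FALSE)
  } else {
    read.csv(path, check.names = FALSE)
  }
  if (!label %in% names(tab)) {
    stop("label column '", label, "' not found in ", path)
  }
  labels <- tab[[label]]
  feats <- tab[setdiff(names(tab), label)]
  bad <- !vapply(feats, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric predictor columns: ",
         paste(names(feats)[bad], collapse = ", "))
  }
  labeled_dataset(as.matrix(feats), labels, k = k)
}

#' Write a labeled dataset to CSV
#'
#' Features plus a final \code{class} column, suitable for fixture capture
#' and for re-reading with \code{\link{read_labeled_dataset}}.
#'
#' @param ds a \code{\link{labeled_dataset}}.
#' @param path output file path.
#' @export
write_labeled_dataset <- function(ds, path) {
  write.csv(as.data.frame(ds), path, row.names = FALSE)
  invisible(path)
}
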