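#' Labeled abundance profiles
#'
#' The package's data container: a samples-by-features numeric matrix of
#' relative abundances together with optional class labels and sample/feature
#' identifiers. All classifier, evaluation and selection machinery consumes
#' this type.
#'
#' @param x numeric matrix (samples in rows, taxa/features in columns), all
#'   values finite.
#' @param labels optional character vector of class labels, one per sample;
#'   `NULL` for unlabeled data (prediction input).
#' @param sample_ids,feature_ids identifiers; default to the matrix dimnames
#'   or generated names.
#' @return an object of class `labeled_profiles` with elements `matrix`,
#'   `labels`, `sample_ids`, `feature_ids`.
#' @export
#' @examples
#' m <- matrix(runif(12, 0, 100), 3, 4)
#' labeled_profiles(m, labels = c("a", "b", "a"))
labeled_profiles <- function(x, labels = NULL, sample_ids = NULL, feature_ids = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix (samples x features)", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("abundance matrix contains missing or non-finite values", call. = FALSE)
  }
  sample_ids <- sample_ids %||% rownames(x) %||% sprintf("sample_%d", seq_len(nrow(x)))
  feature_ids <- feature_ids %||% colnames(x) %||% sprintf("feature_%d", seq_len(ncol(x)))
  if (length(sample_ids) != nrow(x)) stop("sample_ids length != number of rows", call. = FALSE)
  if (length(feature_ids) != ncol(x)) stop("feature_ids length != number of columns", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers", call. = FALSE)
  if (anyDuplicated(feature_ids)) stop("duplicate feature identifiers", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(x)) stop("labels length != number of samples", call. = FALSE)
    if (anyNA(labels)) stop("labels contain missing values", call. = FALSE)
  }
  dimnames(x) <- list(sample_ids, feature_ids)
  structure(
    list(matrix = x, labels = labels,
         sample_ids = as.character(sample_ids),
         feature_ids = as.character(feature_ids)),
    class = "labeled_profiles"
  )
}

#' @export
print.labeled_profiles <- function(x, ...) {
  cat(sprintf("<labeled_profiles> %d samples x %d features\n",
              nrow(x$matrix), ncol(x$matrix)))
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("  classes:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  } else {
    cat("  unlabeled\n")
  }
  invisible(x)
}

#' Subset labeled profiles
#'
#' @param x a [labeled_profiles()] object.
#' @param i sample index (integer/logical vector) or missing.
#' @param j feature selector: integer/logical index or character feature IDs.
#' @param ... unused.
#' @return a `labeled_profiles` restricted to the requested samples/features.
#' @export
`[.labeled_profiles` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$matrix))
  if (missing(j)) j <- seq_len(ncol(x$matrix))
  if (is.character(j)) {
    miss <- setdiff(j, x$feature_ids)
    if (length(miss)) {
      stop(sprintf("unknown feature id(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
    }
    j <- match(j, x$feature_ids)
  }
  m <- x$matrix[i, j, drop = FALSE]
  labeled_profiles(m,
                   labels = if (!is.null(x$labels)) x$labels[i] else NULL,
                   sample_ids = rownames(m), feature_ids = colnames(m))
}

n_samples <- function(data) nrow(data$matrix)
n_features <- function(data) ncol(data$matrix)
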