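# Measurement protocol: F1, stratified k-fold cross-validation, class-balance
# scoring with min-max normalization, the four-way color categorization of
# classifier comparisons, and the significant-feature fraction.

#' F1 score
#'
#' Binary F1 (harmonic mean of precision and recall) for a designated positive
#' label; for more than two classes the macro average (unweighted mean of
#' per-class F1) is returned.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @param positive positive class for the binary case; defaults to the
#'   lexicographically larger of the observed true labels.
#' @return F1 in `[0, 1]`; 0 when precision and recall are both undefined or
#'   zero (no true and no predicted positives).
#' @export
#' @examples
#' f1_score(c("a", "b", "a", "b"), c("a", "b", "b", "b"), positive = "b")
f1_score <- function(y_true, y_pred, positive = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  if (length(y_true) == 0L) stop("empty label vectors", call. = FALSE)
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- sort(unique(y_true))
  if (length(classes) > 2L) {
    return(mean(vapply(classes, function(cl) f1_one(y_true, y_pred, cl), numeric(1))))
  }
  positive <- positive %||% classes[length(classes)]
  f1_one(y_true, y_pred, positive)
}

f1_one <- function(y_true, y_pred, positive) {
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

# deterministic stratified fold assignment: shuffle within class, deal folds
stratified_folds <- function(labels, k, seed) {
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small)) {
    stop(sprintf("class '%s' has fewer than k = %d samples; cannot stratify",
                 small[1], k), call. = FALSE)
  }
  fold <- integer(length(labels))
  run_seeded(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Partitions samples into `k` stratified folds (class proportions preserved;
#' assignment deterministic given `seed`), fits the classifier on each
#' training split and scores F1 on the held-out fold. The positive label is
#' fixed from the full label set so every fold is scored on the same scale.
#'
#' @param data labeled profiles; every class needs at least `k` members.
#' @param classifier a `classifier_spec` (e.g. [hdc_classifier()] or
#'   [make_baseline()]).
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param positive optional positive label passed to [f1_score()].
#' @return a `cv_result`: `fold_scores`, their `mean`, `k`, `seed`,
#'   `classifier` name.
#' @export
cross_validate <- function(data, classifier, k = 5, seed = 1, positive = NULL) {
  stopifnot(inherits(data, "labeled_profiles"), inherits(classifier, "classifier_spec"))
  if (is.null(data$labels)) stop("cross-validation needs labeled data", call. = FALSE)
  k <- assert_count(k, "k", min = 2)
  classes <- sort(unique(data$labels))
  positive <- positive %||% if (length(classes) == 2L) classes[2L] else NULL
  scores <- if (!is.null(classifier$fast_cv)) {
    classifier$fast_cv(data, k, seed, positive)
  } else {
    fold <- stratified_folds(data$labels, k, seed)
    vapply(seq_len(k), function(f) {
      train <- data[fold != f, ]
      test <- data[fold == f, ]
      fit <- classifier$fit(train)
      pred <- classifier$predict(fit, test)
      f1_score(test$labels, pred, positive = positive)
    }, numeric(1))
  }
  structure(list(fold_scores = scores, mean = mean(scores), k = k,
                 seed = as.integer(seed), classifier = classifier$name),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold: mean F1 = %.4f (folds: %s)\n",
              x$classifier, x$k, x$mean,
              paste(sprintf("%.3f", x$fold_scores), collapse = ", ")))
  invisible(x)
}

#' Class-balance score of a binary label vector
#'
#' The minority-class fraction: size of the smaller class divided by the total
#' sample count, in `(0, 0.5]`. Used (after min-max normalization across
#' candidate datasets) to filter studies suitable for classification.
#'
#' @param labels label vector containing exactly two distinct classes.
#' @return the raw balance score.
#' @export
#' @examples
#' balance_score(rep(c("a", "b"), c(25, 75)))  # 0.25
balance_score <- function(labels) {
  counts <- table(as.character(labels))
  if (length(counts) != 2L) {
    stop(sprintf("balance score is defined for exactly 2 classes (got %d)",
                 length(counts)), call. = FALSE)
  }
  as.numeric(min(counts) / sum(counts))
}

#' Min-max normalize a score vector
#'
#' @param raw numeric vector with at least 2 values, not all equal.
#' @return `(x - min) / (max - min)`: the maximum maps to exactly 1, the
#'   minimum to exactly 0.
#' @export
normalize_scores <- function(raw) {
  if (length(raw) < 2L) stop("need at least 2 scores to normalize", call. = FALSE)
  lo <- min(raw)
  hi <- max(raw)
  if (hi == lo) stop("min-max normalization undefined: all scores equal", call. = FALSE)
  (raw - lo) / (hi - lo)
}

#' Categorize an HDC-vs-baselines comparison
#'
#' The four-color rule used when comparing the HDC F1 against classical
#' classifiers, with margin threshold `tau` (default 0.05). Evaluated in
#' order: *violet* when HDC beats every baseline by more than `tau`; else
#' *black* when any baseline beats HDC by more than `tau`; else *red* when
#' HDC beats at least one baseline by more than `tau`; else *blue*
#' (everything within the margin). The black-before-red precedence resolves
#' the overlap between "beats at least one" and "beaten by at least one"
#' conservatively against HDC.
#'
#' @param hdc HDC score.
#' @param baselines named numeric vector of baseline scores (non-empty).
#' @param tau comparability threshold (default 0.05).
#' @return a `comparison_outcome`: `category`, `hdc_score`, `baseline_scores`,
#'   `threshold`.
#' @export
#' @examples
#' categorize_comparison(0.69, c(LRC = 0.55, DTC = 0.49, SVC = 0.50, RFC = 0.60))
categorize_comparison <- function(hdc, baselines, tau = 0.05) {
  if (length(baselines) < 1L) stop("need at least one baseline score", call. = FALSE)
  stopifnot(is.numeric(hdc), length(hdc) == 1L, is.numeric(baselines), tau >= 0)
  category <- if (all(hdc - baselines > tau)) {
    "violet"
  } else if (any(baselines - hdc > tau)) {
    "black"
  } else if (any(hdc - baselines > tau)) {
    "red"
  } else {
    "blue"
  }
  structure(list(category = category, hdc_score = hdc,
                 baseline_scores = baselines, threshold = tau),
            class = "comparison_outcome")
}

#' @export
print.comparison_outcome <- function(x, ...) {
  cat(sprintf("<comparison_outcome> %s: HDC %.3f vs %s (tau = %g)\n",
              x$category, x$hdc_score,
              paste(sprintf("%s %.3f", names(x$baseline_scores), x$baseline_scores),
                    collapse = ", "),
              x$threshold))
  invisible(x)
}

#' Fraction of features that significantly separate the two classes
#'
#' Applies a two-sample Wilcoxon rank-sum (Mann–Whitney) test to each listed
#' feature between the two classes and reports the percentage with p below
#' `alpha`. The tie-corrected normal approximation is used, as abundance data
#' carries many tied zeros.
#'
#' @param data labeled profiles with exactly 2 classes.
#' @param features feature IDs to test (default: all features); must be
#'   non-empty and a subset of the data's features.
#' @param alpha significance threshold (default 0.05).
#' @return percentage in `[0, 100]`.
#' @export
significant_feature_fraction <- function(data, features = NULL, alpha = 0.05) {
  stopifnot(inherits(data, "labeled_profiles"))
  if (is.null(data$labels)) stop("needs labeled data", call. = FALSE)
  classes <- sort(unique(data$labels))
  if (length(classes) != 2L) stop("needs exactly 2 classes", call. = FALSE)
  features <- features %||% data$feature_ids
  if (length(features) == 0L) stop("empty feature set", call. = FALSE)
  miss <- setdiff(features, data$feature_ids)
  if (length(miss)) {
    stop(sprintf("unknown feature id(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  }
  g1 <- data$labels == classes[1]
  p <- vapply(features, function(f) {
    x <- data$matrix[g1, f]
    y <- data$matrix[!g1, f]
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1  # degenerate features (e.g. all-tied zeros) are never significant
  100 * mean(p < alpha)
}
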