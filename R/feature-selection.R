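# Backward variable elimination tailored to the fit/predict contract. From
# the current surviving set F, every leave-one-out candidate F \ {f} is
# scored; the candidates within tolerance of the best score are "best
# models", and the next surviving set is the intersection of their feature
# sets (equivalently F minus every best-removed feature). A feature's
# importance is the iteration at which it was discarded: the later, the more
# the classifier depended on it.

#' Feature-selection configuration
#'
#' @param evaluator `function(data) -> numeric score` (higher is better)
#'   scoring a candidate feature subset. Default `NULL` builds the standard
#'   evaluator: mean F1 over stratified `folds`-fold cross-validation of
#'   `classifier`.
#' @param classifier a `classifier_spec` used by the default evaluator
#'   (default [hdc_classifier()]).
#' @param folds CV folds for the default evaluator (default 5).
#' @param tie_tol score tolerance for counting candidates as tied-best
#'   (default 1e-9, i.e. exact ties up to float noise).
#' @param min_features stop once the surviving set has at most this many
#'   features (default 1: a zero-feature model is unevaluable).
#' @param seed seed for the default evaluator's fold assignment.
#' @return a `selection_config`.
#' @export
selection_config <- function(evaluator = NULL, classifier = NULL, folds = 5,
                             tie_tol = 1e-9, min_features = 1, seed = 1) {
  if (!is.null(evaluator)) stopifnot(is.function(evaluator))
  if (!is.null(classifier)) stopifnot(inherits(classifier, "classifier_spec"))
  stopifnot(tie_tol >= 0)
  assert_count(folds, "folds", min = 2)
  assert_count(min_features, "min_features", min = 1)
  structure(list(evaluator = evaluator, classifier = classifier,
                 folds = as.integer(folds), tie_tol = tie_tol,
                 min_features = as.integer(min_features),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Backward variable elimination
#'
#' Starting from all `M` features, each iteration scores one candidate model
#' per surviving feature (trained on the set minus that feature), keeps the
#' candidates within `tie_tol` of the best score, and intersects their
#' feature sets to form the next surviving set — so at least one feature is
#' discarded per iteration and the procedure terminates in at most
#' `M - min_features` iterations. Discarded features are stamped with the
#' iteration index; features still alive at the end are the final survivors
#' (most important of all).
#'
#' @param data labeled profiles with `M >= 2` features.
#' @param config a [selection_config()].
#' @return an `elimination_trace`: `iterations` (per-iteration records with
#'   `surviving`, per-candidate `scores`, `best_score`, `best_removed`,
#'   `next_surviving`), `importance` (named integer vector: discard
#'   iteration per discarded feature), `final_survivors`.
#' @export
#' @examples
#' syn <- generate_profiles(synthetic_spec(n_per_class = c(15, 15),
#'   n_features = 6, n_informative = 2, seed = 4))
#' cfg <- selection_config(classifier = hdc_classifier(encoding_config(500, 10)),
#'   folds = 3)
#' tr <- backward_eliminate(syn$profiles, cfg)
backward_eliminate <- function(data, config = selection_config()) {
  stopifnot(inherits(data, "labeled_profiles"), inherits(config, "selection_config"))
  if (ncol(data$matrix) < 2L) {
    stop("backward elimination needs at least 2 features", call. = FALSE)
  }
  evaluator <- config$evaluator
  if (is.null(evaluator)) {
    classifier <- config$classifier %||% hdc_classifier()
    cv_seed <- derive_seed(config$seed, "elimination-cv")
    evaluator <- function(d) {
      cross_validate(d, classifier, k = config$folds, seed = cv_seed)$mean
    }
  }

  surviving <- data$feature_ids
  iterations <- list()
  importance <- integer(0)
  it <- 0L
  while (length(surviving) > config$min_features) {
    it <- it + 1L
    scores <- vapply(surviving, function(f) {
      tryCatch(evaluator(data[, setdiff(surviving, f)]),
               error = function(e) {
                 stop(sprintf("evaluator failed at iteration %d (removing '%s'): %s",
                              it, f, conditionMessage(e)), call. = FALSE)
               })
    }, numeric(1))
    best_score <- max(scores)
    best_removed <- surviving[scores >= best_score - config$tie_tol]
    next_surviving <- setdiff(surviving, best_removed)
    importance[best_removed] <- it
    iterations[[it]] <- list(surviving = surviving, scores = scores,
                             best_score = best_score, best_removed = best_removed,
                             next_surviving = next_surviving)
    surviving <- next_surviving
    if (length(surviving) == 0L) break
  }
  structure(list(iterations = iterations, importance = importance,
                 final_survivors = surviving),
            class = "elimination_trace")
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf("<elimination_trace> %d iterations, %d discarded, %d survivors\n",
              length(x$iterations), length(x$importance), length(x$final_survivors)))
  invisible(x)
}

#' Select the final feature set from an elimination trace
#'
#' Picks the surviving set produced by the iteration with the maximum best
#' score across all iterations (i.e. the set entering the following
#' iteration); ties are broken toward the smallest (latest) set.
#'
#' @param trace an [backward_eliminate()] trace with at least one iteration.
#' @return character vector of selected feature IDs.
#' @export
select_features <- function(trace) {
  stopifnot(inherits(trace, "elimination_trace"))
  if (length(trace$iterations) == 0L) stop("empty elimination trace", call. = FALSE)
  best_scores <- vapply(trace$iterations, `[[`, numeric(1), "best_score")
  best <- max(best_scores)
  t_star <- max(which(best_scores == best))  # latest max = smallest set
  trace$iterations[[t_star]]$next_surviving
}

#' Per-feature importance scores from an elimination trace
#'
#' Importance is the discard iteration; features never discarded (final
#' survivors) score one more than the last iteration, ranking above
#' everything discarded.
#'
#' @param trace an elimination trace.
#' @return a data.frame with `feature_id`, `discard_iteration` (`NA` for
#'   survivors) and numeric `importance`, sorted by decreasing importance.
#' @export
feature_importance <- function(trace) {
  stopifnot(inherits(trace, "elimination_trace"))
  n_it <- length(trace$iterations)
  ids <- c(names(trace$importance), trace$final_survivors)
  disc <- c(as.integer(trace$importance), rep(NA_integer_, length(trace$final_survivors)))
  imp <- ifelse(is.na(disc), n_it + 1L, disc)
  out <- data.frame(feature_id = ids, discard_iteration = disc,
                    importance = as.numeric(imp), stringsAsFactors = FALSE)
  out[order(-out$importance, out$feature_id), , drop = FALSE]
}

#' Export an elimination trace as tab-separated tables
#'
#' Writes the per-candidate score table (columns `iteration`,
#' `removed_feature`, `score`, `is_best`, `surviving_count`) to `path` and,
#' optionally, the importance table to `importance_path`.
#'
#' @param trace an elimination trace.
#' @param path output TSV path for the per-iteration candidate records.
#' @param importance_path optional output TSV for [feature_importance()].
#' @return `path`, invisibly.
#' @export
write_elimination_trace <- function(trace, path, importance_path = NULL) {
  stopifnot(inherits(trace, "elimination_trace"))
  rows <- do.call(rbind, lapply(seq_along(trace$iterations), function(i) {
    rec <- trace$iterations[[i]]
    data.frame(iteration = i,
               removed_feature = names(rec$scores),
               score = unname(rec$scores),
               is_best = names(rec$scores) %in% rec$best_removed,
               surviving_count = length(rec$next_surviving),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(importance_path)) {
    utils::write.table(feature_importance(trace), importance_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  invisible(path)
}
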