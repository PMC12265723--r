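# Associative-memory HDC classifier. Training bundles every encoded sample
# into its class hypervector; prediction returns the class whose hypervector
# is closest in cosine similarity; retraining iteratively moves misclassified
# sample vectors from the wrongly predicted class to the true one.

# cosine similarities between rows of S (n x d) and rows of C (k x d);
# zero-norm rows yield similarity 0 by contract
cosine_rows <- function(S, C) {
  storage.mode(S) <- "double"
  storage.mode(C) <- "double"
  sn <- sqrt(rowSums(S * S))
  cn <- sqrt(rowSums(C * C))
  sims <- S %*% t(C)
  denom <- outer(sn, cn)
  out <- matrix(0, nrow(sims), ncol(sims), dimnames = dimnames(sims))
  nz <- denom > 0
  out[nz] <- sims[nz] / denom[nz]
  out
}

# argmax by cosine with ties broken toward the first (ascending-sorted) label
predict_from_encodings <- function(class_vectors, S) {
  sims <- cosine_rows(S, class_vectors)
  rownames(class_vectors)[max.col(sims, ties.method = "first")]
}

#' Fit the HDC associative-memory classifier
#'
#' Builds the level-vector set from `config` (resolving the quantization range
#' from the training data when unset), encodes every training sample, and
#' bundles the encodings class-wise: the class hypervector is
#' \eqn{C_c = \sum_{i: y_i = c} S_i}. Integer bundling commutes, so the model
#' is independent of sample order and fully deterministic given the seed.
#'
#' @param data a [labeled_profiles()] object with labels from at least 2
#'   classes and at least one sample per class.
#' @param config an [encoding_config()].
#' @return an `hdc_model`: class vectors (rows sorted by label), the level
#'   set, the resolved config, feature ids, and an empty retraining history.
#' @export
#' @examples
#' syn <- generate_profiles(synthetic_spec(n_per_class = c(20, 20),
#'   n_features = 10, seed = 1))
#' fit <- hdc_fit(syn$profiles, encoding_config(2000, 20))
hdc_fit <- function(data, config = encoding_config()) {
  stopifnot(inherits(data, "labeled_profiles"), inherits(config, "encoding_config"))
  if (is.null(data$labels)) stop("training data must be labeled", call. = FALSE)
  classes <- sort(unique(data$labels))
  if (length(classes) < 2L) {
    stop("training data must contain at least 2 classes", call. = FALSE)
  }
  config <- resolve_encoding_range(config, data$matrix)
  level_set <- build_level_vectors(config)
  S <- encode_profiles(data$matrix, level_set)
  C <- rowsum(S, group = factor(data$labels, levels = classes), reorder = TRUE)
  storage.mode(C) <- "double"
  rownames(C) <- classes
  structure(list(class_vectors = C, level_set = level_set, config = config,
                 feature_ids = data$feature_ids,
                 n_features = ncol(data$matrix),
                 retrain_history = numeric(0),
                 accepted_iteration = NA_integer_),
            class = "hdc_model")
}

#' @export
print.hdc_model <- function(x, ...) {
  cat(sprintf("<hdc_model> %d classes (%s), D = %d, M = %d features\n",
              nrow(x$class_vectors), paste(rownames(x$class_vectors), collapse = ", "),
              x$level_set$d, x$n_features))
  if (length(x$retrain_history)) {
    cat(sprintf("  retrained: error %s (accepted pass %d)\n",
                paste(signif(x$retrain_history, 3), collapse = " -> "),
                x$accepted_iteration))
  }
  invisible(x)
}

check_model_data <- function(model, data) {
  if (ncol(data$matrix) != model$n_features) {
    stop(sprintf("feature-count mismatch: model has %d features, data has %d",
                 model$n_features, ncol(data$matrix)), call. = FALSE)
  }
}

#' Predict class labels with a fitted HDC model
#'
#' Each sample is encoded with the model's level set and assigned the label of
#' the class hypervector with the highest cosine similarity; exact ties go to
#' the first label in ascending sort order.
#'
#' @param object an `hdc_model`.
#' @param newdata a [labeled_profiles()] object (labels optional) with the
#'   model's feature count.
#' @param similarities if `TRUE`, attach the raw per-class cosine matrix as
#'   attribute `"similarities"` (uncalibrated, for inspection only).
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.hdc_model <- function(object, newdata, similarities = FALSE, ...) {
  stopifnot(inherits(newdata, "labeled_profiles"))
  check_model_data(object, newdata)
  S <- encode_profiles(newdata$matrix, object$level_set)
  sims <- cosine_rows(S, object$class_vectors)
  pred <- rownames(object$class_vectors)[max.col(sims, ties.method = "first")]
  names(pred) <- newdata$sample_ids
  if (similarities) attr(pred, "similarities") <- sims
  pred
}

#' Training/evaluation error rate of an HDC model
#'
#' @param model an `hdc_model`.
#' @param data labeled profiles.
#' @return misclassified fraction in `[0, 1]`.
#' @export
hdc_error_rate <- function(model, data) {
  stopifnot(inherits(data, "labeled_profiles"))
  if (is.null(data$labels) || nrow(data$matrix) == 0L) {
    stop("error rate needs a non-empty labeled dataset", call. = FALSE)
  }
  mean(predict(model, data) != data$labels)
}

# one correction pass: add each misclassified sample's encoding to its true
# class vector and subtract it from the wrongly predicted one (exact integers)
hdc_correction_step <- function(class_vectors, S, labels, predictions) {
  mis <- predictions != labels
  for (cl in rownames(class_vectors)) {
    gain <- mis & labels == cl
    loss <- mis & predictions == cl
    if (any(gain)) class_vectors[cl, ] <- class_vectors[cl, ] + colSums(S[gain, , drop = FALSE])
    if (any(loss)) class_vectors[cl, ] <- class_vectors[cl, ] - colSums(S[loss, , drop = FALSE])
  }
  class_vectors
}

#' Iteratively retrain an HDC model on its training data
#'
#' Bundling many samples into one class vector accumulates crosstalk noise;
#' retraining mitigates it. Sample encodings are computed once; each pass
#' predicts all training samples, then adds every misclassified encoding to
#' its true class vector and subtracts it from the wrongly predicted one.
#' Passes stop when the training error reaches 0, fails to decrease, or
#' `max_iterations` corrections have been applied. The returned model carries
#' the lowest-error snapshot observed (so retraining can never hand back a
#' model worse than its input), the full per-pass error history in
#' `retrain_history`, and the index of the accepted pass.
#'
#' @param model an `hdc_model` fitted on `data`.
#' @param data the model's training set.
#' @param max_iterations safety cap on correction passes (default 100).
#' @return the retrained `hdc_model`.
#' @export
hdc_retrain <- function(model, data, max_iterations = 100) {
  stopifnot(inherits(model, "hdc_model"), inherits(data, "labeled_profiles"))
  if (is.null(data$labels)) stop("retraining needs labeled data", call. = FALSE)
  check_model_data(model, data)
  if (!all(sort(unique(data$labels)) %in% rownames(model$class_vectors))) {
    stop("data contains labels unknown to the model", call. = FALSE)
  }
  assert_count(max_iterations, "max_iterations", min = 1)

  S <- encode_profiles(data$matrix, model$level_set)
  storage.mode(S) <- "double"
  cur <- model$class_vectors
  best <- cur
  best_err <- Inf
  last_err <- Inf
  accepted <- 1L
  history <- numeric(0)
  iter <- 0L
  repeat {
    pred <- predict_from_encodings(cur, S)
    err <- mean(pred != data$labels)
    history <- c(history, err)
    if (err < best_err) {
      best_err <- err
      best <- cur
      accepted <- length(history)
    }
    if (err == 0 || err >= last_err || iter >= max_iterations) break
    last_err <- err
    cur <- hdc_correction_step(cur, S, data$labels, pred)
    iter <- iter + 1L
  }
  model$class_vectors <- best
  model$retrain_history <- history
  model$accepted_iteration <- accepted
  model
}

#' HDC classifier factory for the cross-validation / selection machinery
#'
#' Wraps [hdc_fit()] (optionally followed by [hdc_retrain()]) in the common
#' fit/predict contract shared with the baseline adapters, so the HDC model
#' plugs into [cross_validate()] and [backward_eliminate()] interchangeably.
#'
#' @param config an [encoding_config()].
#' @param retrain apply iterative retraining after fitting (default `FALSE`).
#' @param max_iterations retraining cap, see [hdc_retrain()].
#' @return a `classifier_spec` (fields `name`, `fit`, `predict`).
#' @export
hdc_classifier <- function(config = encoding_config(), retrain = FALSE,
                           max_iterations = 100) {
  force(config); force(retrain); force(max_iterations)
  # With an explicit quantization range the encoding of a sample does not
  # depend on the training split, so cross-validation can encode every sample
  # once and assemble each fold's class vectors by row sums — bit-identical
  # to refitting per fold, but O(k) cheaper. Retraining and data-resolved
  # ranges fall back to the generic fold loop.
  fast_cv <- NULL
  if (!retrain && !is.null(config$value_min)) {
    fast_cv <- function(data, k, seed, positive) {
      fold <- stratified_folds(data$labels, k, seed)
      level_set <- build_level_vectors(config)
      S <- encode_profiles(data$matrix, level_set)
      classes <- sort(unique(data$labels))
      vapply(seq_len(k), function(f) {
        train <- fold != f
        C <- rowsum(S[train, , drop = FALSE],
                    group = factor(data$labels[train], levels = classes))
        pred <- predict_from_encodings(C, S[!train, , drop = FALSE])
        f1_score(data$labels[!train], pred, positive = positive)
      }, numeric(1))
    }
  }
  spec <- classifier_spec(
    name = "HDC",
    fit = function(data) {
      m <- hdc_fit(data, config)
      if (retrain) m <- hdc_retrain(m, data, max_iterations)
      m
    },
    predict = function(model, data) predict(model, data),
    fast_cv = fast_cv
  )
  spec$config <- config
  spec$retrain <- retrain
  spec
}
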