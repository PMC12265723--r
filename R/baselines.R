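# Pluggable classifier adapters. Everything that trains and predicts — the
# HDC model and the classical baselines alike — is wrapped in the same small
# fit/predict contract so cross-validation, comparison and backward
# elimination never care which algorithm they are driving.

#' Construct a classifier specification
#'
#' The common contract: `fit(data)` takes [labeled_profiles()] and returns an
#' opaque fitted object; `predict(model, data)` returns a character label per
#' sample.
#'
#' @param name display name.
#' @param fit,predict functions implementing the contract.
#' @param fast_cv optional `function(data, k, seed, positive)` returning the
#'   per-fold F1 vector of a stratified k-fold cross-validation, for
#'   classifiers that can share work across folds; must reproduce the
#'   generic fold loop exactly (same fold assignment, same scores).
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(name, fit, predict, fast_cv = NULL) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  if (!is.null(fast_cv)) stopifnot(is.function(fast_cv))
  structure(list(name = name, fit = fit, predict = predict, fast_cv = fast_cv),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("<classifier_spec> %s\n", x$name))
  invisible(x)
}

# features get positional names so baseline formulas never choke on taxon ids
baseline_frame <- function(data) {
  df <- as.data.frame(data$matrix)
  names(df) <- sprintf("f%d", seq_len(ncol(df)))
  df
}

.baseline_registry <- new.env(parent = emptyenv())

#' Register a custom baseline factory
#'
#' @param name registry key (lower-case).
#' @param factory `function(hyperparameters, seed)` returning a
#'   [classifier_spec()].
#' @export
register_baseline <- function(name, factory) {
  stopifnot(is.character(name), is.function(factory))
  assign(tolower(name), factory, envir = .baseline_registry)
  invisible(name)
}

builtin_baselines <- function() c("lrc", "dtc", "svc", "rfc", "majority")

#' Create a baseline classifier adapter
#'
#' Thin adapters delegating to established implementations: `"lrc"` logistic
#' regression (`stats::glm`, binomial), `"dtc"` decision tree
#' (`rpart::rpart`), `"svc"` support vector machine (`e1071::svm`, radial
#' kernel), `"rfc"` random forest (`ranger::ranger`, single-threaded for
#' determinism), and `"majority"` (always predicts the most frequent training
#' label; ties to the first label in sort order — a degenerate reference).
#' Hyperparameters default to the delegated library's defaults and are kept
#' in the adapter for provenance.
#'
#' @param name one of `"lrc"`, `"dtc"`, `"svc"`, `"rfc"`, `"majority"`
#'   (case-insensitive), or a name registered via [register_baseline()].
#' @param hyperparameters named list forwarded to the underlying fit call.
#' @param seed integer seed applied around each fit for reproducibility.
#' @return a `classifier_spec` with a `hyperparameters` field.
#' @export
#' @examples
#' rfc <- make_baseline("rfc", seed = 1)
make_baseline <- function(name, hyperparameters = list(), seed = 1) {
  key <- tolower(name)
  if (exists(key, envir = .baseline_registry, inherits = FALSE)) {
    return(get(key, envir = .baseline_registry)(hyperparameters, seed))
  }
  spec <- switch(key,
    lrc = baseline_lrc(hyperparameters, seed),
    dtc = baseline_dtc(hyperparameters, seed),
    svc = baseline_svc(hyperparameters, seed),
    rfc = baseline_rfc(hyperparameters, seed),
    majority = baseline_majority(hyperparameters, seed),
    stop(sprintf("unknown baseline '%s'; registered baselines: %s", name,
                 paste(c(builtin_baselines(),
                         ls(envir = .baseline_registry)), collapse = ", ")),
         call. = FALSE)
  )
  spec$hyperparameters <- hyperparameters
  spec$seed <- as.integer(seed)
  spec
}

baseline_lrc <- function(hp, seed) {
  classifier_spec(
    name = "LRC",
    fit = function(data) {
      classes <- sort(unique(data$labels))
      if (length(classes) != 2L) {
        stop("the logistic-regression baseline supports binary labels only",
             call. = FALSE)
      }
      df <- baseline_frame(data)
      df$.y <- factor(data$labels, levels = classes)
      fit <- run_seeded(seed, suppressWarnings(
        do.call(stats::glm,
                c(list(formula = .y ~ ., family = stats::binomial(), data = df), hp))
      ))
      list(fit = fit, classes = classes)
    },
    predict = function(model, data) {
      p <- suppressWarnings(
        stats::predict(model$fit, newdata = baseline_frame(data), type = "response"))
      model$classes[(p > 0.5) + 1L]
    }
  )
}

baseline_dtc <- function(hp, seed) {
  classifier_spec(
    name = "DTC",
    fit = function(data) {
      df <- baseline_frame(data)
      df$.y <- factor(data$labels)
      run_seeded(seed,
        do.call(rpart::rpart, c(list(formula = .y ~ ., data = df, method = "class"), hp)))
    },
    predict = function(model, data) {
      as.character(stats::predict(model, newdata = baseline_frame(data), type = "class"))
    }
  )
}

baseline_svc <- function(hp, seed) {
  classifier_spec(
    name = "SVC",
    fit = function(data) {
      run_seeded(seed,
        do.call(e1071::svm,
                c(list(x = data$matrix, y = factor(data$labels)), hp)))
    },
    predict = function(model, data) {
      as.character(stats::predict(model, newdata = data$matrix))
    }
  )
}

baseline_rfc <- function(hp, seed) {
  classifier_spec(
    name = "RFC",
    fit = function(data) {
      df <- baseline_frame(data)
      df$.y <- factor(data$labels)
      do.call(ranger::ranger,
              c(list(dependent.variable.name = ".y", data = df,
                     seed = seed, num.threads = 1L), hp))
    },
    predict = function(model, data) {
      as.character(stats::predict(model, data = baseline_frame(data),
                                  num.threads = 1L)$predictions)
    }
  )
}

baseline_majority <- function(hp, seed) {
  classifier_spec(
    name = "majority",
    fit = function(data) {
      counts <- table(data$labels)
      names(counts)[which.max(counts)]  # table is sorted: ties go to first label
    },
    predict = function(model, data) rep(model, nrow(data$matrix))
  )
}
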