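# Small in-code fixtures shared across test files.

# a deterministic, clearly separable two-class toy set: class "a" abundant in
# the first features, class "b" in the last ones
toy_profiles <- function(n_per_class = 6, m = 8, seed = 42) {
  withr_seed <- function(expr) hdclassify:::run_seeded(seed, expr)
  withr_seed({
    x <- matrix(runif(2 * n_per_class * m, 0, 5), 2 * n_per_class, m)
    half <- seq_len(m %/% 2)
    x[seq_len(n_per_class), half] <- x[seq_len(n_per_class), half] + 60
    x[-seq_len(n_per_class), -half] <- x[-seq_len(n_per_class), -half] + 60
    labeled_profiles(x, labels = rep(c("a", "b"), each = n_per_class))
  })
}

small_config <- function(d = 1000, m = 20, seed = 7, ...) {
  encoding_config(dimensionality = d, levels = m, seed = seed, ...)
}

# independent brute-force re-implementation of cosine-argmax prediction used
# as the oracle for predict(): plain R loops, no shared code path
oracle_predict <- function(model, data) {
  lv <- model$level_set
  labels_sorted <- sort(rownames(model$class_vectors))
  out <- character(nrow(data$matrix))
  for (i in seq_len(nrow(data$matrix))) {
    s <- numeric(lv$d)
    for (j in seq_len(ncol(data$matrix))) {
      x <- data$matrix[i, j]
      idx <- floor((x - lv$value_min) / (lv$value_max - lv$value_min) * lv$m)
      idx <- min(max(idx, 0), lv$m - 1)
      vec <- lv$levels[idx + 1, ]
      k <- (j - 1) %% lv$d
      if (k > 0) vec <- c(vec[(lv$d - k + 1):lv$d], vec[1:(lv$d - k)])
      s <- s + vec
    }
    best_lab <- NA_character_
    best_sim <- -Inf
    for (lab in labels_sorted) {
      cvec <- model$class_vectors[lab, ]
      denom <- sqrt(sum(s^2)) * sqrt(sum(cvec^2))
      sim <- if (denom == 0) 0 else sum(s * cvec) / denom
      if (sim > best_sim) {  # strict: first label in sort order wins ties
        best_sim <- sim
        best_lab <- lab
      }
    }
    out[i] <- best_lab
  }
  out
}
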