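test_that("class vectors are exact bundles of their samples' encodings", {
  data <- toy_profiles(n_per_class = 1, m = 6)
  cfg <- small_config(d = 500, m = 10)
  model <- hdc_fit(data, cfg)
  for (lab in c("a", "b")) {
    enc <- encode_sample(data$matrix[data$labels == lab, ], model$level_set)
    expect_identical(as.integer(model$class_vectors[lab, ]), as.integer(enc))
  }

  data4 <- toy_profiles(n_per_class = 4, m = 6)
  model4 <- hdc_fit(data4, cfg)
  S <- encode_profiles(data4$matrix, model4$level_set)
  expect_identical(model4$class_vectors["a", ],
                   unname(colSums(S[data4$labels == "a", ]) + 0))
})

test_that("fitting is invariant to training-row order and seed-deterministic", {
  data <- toy_profiles(n_per_class = 5, m = 8)
  cfg <- small_config(d = 800, m = 15)
  m1 <- hdc_fit(data, cfg)
  perm <- c(7, 2, 9, 1, 10, 4, 3, 8, 5, 6)
  m2 <- hdc_fit(data[perm, ], cfg)
  expect_identical(m1$class_vectors, m2$class_vectors)
  expect_identical(m1$class_vectors, hdc_fit(data, cfg)$class_vectors)
})

test_that("fit rejects degenerate inputs", {
  data <- toy_profiles()
  one_class <- data
  one_class$labels <- rep("a", length(data$labels))
  expect_error(hdc_fit(one_class, small_config()), "at least 2 classes")
  unlabeled <- data
  unlabeled$labels <- NULL
  expect_error(hdc_fit(unlabeled, small_config()), "labeled")
})

test_that("prediction retrieves training samples and breaks ties by label order", {
  data <- toy_profiles(n_per_class = 1, m = 6)
  model <- hdc_fit(data, small_config(d = 500, m = 10))
  expect_identical(unname(predict(model, data)), data$labels)

  # identical class vectors: every sample must fall to the first label
  tied <- model
  tied$class_vectors["b", ] <- tied$class_vectors["a", ]
  expect_identical(unname(predict(tied, data)), rep("a", 2))

  wrong_m <- toy_profiles(n_per_class = 1, m = 4)
  expect_error(predict(model, wrong_m), "feature-count mismatch")
})

test_that("prediction agrees with a brute-force cosine-argmax oracle", {
  for (s in 1:10) {
    syn <- generate_profiles(synthetic_spec(
      n_per_class = c(10, 10), n_features = 8, n_informative = 3, seed = s))
    model <- hdc_fit(syn$profiles, small_config(d = 64, m = 10, seed = s))
    expect_identical(unname(predict(model, syn$profiles)),
                     oracle_predict(model, syn$profiles))
  }
})

test_that("error rate is the misclassified fraction", {
  data <- toy_profiles(n_per_class = 2, m = 8)
  model <- hdc_fit(data, small_config())
  pred <- predict(model, data)
  expect_equal(hdc_error_rate(model, data), mean(pred != data$labels))
  # forced all-wrong model: swap the class vectors of a perfect model
  if (hdc_error_rate(model, data) == 0) {
    swapped <- model
    swapped$class_vectors <- model$class_vectors[c("b", "a"), ]
    rownames(swapped$class_vectors) <- c("a", "b")
    expect_equal(hdc_error_rate(swapped, data), 1.0)
  }
  empty <- data[integer(0), ]
  expect_error(hdc_error_rate(model, empty), "non-empty")
})

test_that("a converged model passes through retraining unchanged", {
  data <- toy_profiles(n_per_class = 4, m = 8)
  model <- hdc_fit(data, small_config(d = 2000, m = 20))
  expect_equal(hdc_error_rate(model, data), 0)
  rt <- hdc_retrain(model, data)
  expect_identical(rt$class_vectors, model$class_vectors)
  expect_identical(rt$retrain_history, 0)
  expect_identical(rt$accepted_iteration, 1L)
})

test_that("one correction pass moves misclassified encodings between classes exactly", {
  data <- toy_profiles(n_per_class = 3, m = 8)
  model <- hdc_fit(data, small_config(d = 500, m = 10))
  S <- encode_profiles(data$matrix, model$level_set)
  storage.mode(S) <- "double"
  # corrupt the model so at least one sample misclassifies
  bad <- model$class_vectors
  bad["a", ] <- bad["a", ] - 3 * S[1, ]
  pred <- hdclassify:::predict_from_encodings(bad, S)
  expect_true(any(pred != data$labels))
  stepped <- hdclassify:::hdc_correction_step(bad, S, data$labels, pred)
  expected <- bad
  for (i in which(pred != data$labels)) {
    expected[data$labels[i], ] <- expected[data$labels[i], ] + S[i, ]
    expected[pred[i], ] <- expected[pred[i], ] - S[i, ]
  }
  expect_identical(stepped, expected)
})

test_that("retraining never returns a worse model and logs a decreasing history", {
  worse <- 0
  for (s in 1:25) {
    syn <- generate_profiles(synthetic_spec(
      n_per_class = c(15, 15), n_features = 20, n_informative = 4,
      effect = 1, seed = s))
    cfg <- small_config(d = 600, m = 25, seed = s)
    model <- hdc_fit(syn$profiles, cfg)
    rt <- hdc_retrain(model, syn$profiles, max_iterations = 30)
    e0 <- hdc_error_rate(model, syn$profiles)
    e1 <- hdc_error_rate(rt, syn$profiles)
    expect_lte(e1, e0)
    acc <- rt$accepted_iteration
    expect_equal(rt$retrain_history[acc], min(rt$retrain_history))
    if (acc > 1) {
      expect_true(all(diff(rt$retrain_history[1:acc]) < 0))
    }
    worse <- worse + (e1 > e0)
  }
  expect_identical(worse, 0)
})

test_that("capacity sanity: bundled random samples are retrievable by class", {
  d <- 1000
  x <- hdclassify:::run_seeded(99, matrix(runif(40 * 30, 0, 100), 40, 30))
  data <- labeled_profiles(x, labels = rep(c("g1", "g2"), each = 20))
  model <- hdc_fit(data, encoding_config(d, 50, value_min = 0, value_max = 100, seed = 1))
  expect_gte(1 - hdc_error_rate(model, data), 0.95)
})

test_that("fit -> predict -> retrain is reproducible end to end", {
  syn <- generate_profiles(synthetic_spec(n_per_class = c(12, 12),
                                          n_features = 15, seed = 31))
  cfg <- small_config(d = 700, m = 30, seed = 5)
  run <- function() {
    m <- hdc_fit(syn$profiles, cfg)
    r <- hdc_retrain(m, syn$profiles, max_iterations = 10)
    list(p = predict(m, syn$profiles), cv = r$class_vectors, h = r$retrain_history)
  }
  expect_identical(run(), run())
})
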