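# cheap deterministic evaluators keep the combinatorics tests fast
score_by_ids <- function(weights) {
  function(data) sum(weights[data$feature_ids])
}

flat_evaluator <- function(data) 0.5

test_that("the first iteration scores one leave-one-out candidate per feature", {
  data <- toy_profiles(n_per_class = 3, m = 10)
  w <- stats::setNames(seq_len(10), data$feature_ids)  # drop-lowest-id preference
  cfg <- selection_config(evaluator = score_by_ids(w), seed = 1)
  tr <- backward_eliminate(data, cfg)
  it1 <- tr$iterations[[1]]
  expect_length(it1$scores, 10)
  expect_setequal(names(it1$scores), data$feature_ids)
  # removing feature 1 keeps the largest total weight -> it is discarded first
  expect_identical(it1$best_removed, data$feature_ids[1])
  expect_length(it1$next_surviving, 9)
})

test_that("elimination shrinks strictly, terminates, and importance is total", {
  data <- toy_profiles(n_per_class = 3, m = 12)
  w <- stats::setNames(c(5, 1, 9, 2, 8, 3, 7, 4, 6, 10, 11, 12), data$feature_ids)
  tr <- backward_eliminate(data, selection_config(evaluator = score_by_ids(w)))
  sizes <- vapply(tr$iterations, function(it) length(it$surviving), integer(1))
  expect_true(all(diff(sizes) < 0))
  expect_lte(length(tr$iterations), 11)  # at most M - min_features iterations
  accounted <- c(names(tr$importance), tr$final_survivors)
  expect_setequal(accounted, data$feature_ids)
  expect_length(accounted, 12)
  # higher weight = more valuable = discarded later
  expect_identical(tr$final_survivors, data$feature_ids[12])
  imp <- feature_importance(tr)
  expect_identical(imp$feature_id[1], data$feature_ids[12])
  expect_identical(unname(tr$importance[data$feature_ids[2]]), 1L)  # least valuable first
})

test_that("tied best candidates shrink the surviving set by the whole tie group", {
  data <- toy_profiles(n_per_class = 3, m = 8)
  # all candidates identical: intersection of all leave-one-out sets is empty
  tr <- backward_eliminate(data, selection_config(evaluator = flat_evaluator))
  expect_length(tr$iterations, 1)
  expect_identical(tr$iterations[[1]]$best_removed, data$feature_ids)
  expect_length(tr$final_survivors, 0)
  expect_setequal(names(tr$importance), data$feature_ids)

  # two-way tie: drop exactly the two tied features
  w <- stats::setNames(c(1, 1, 5, 6, 7, 8, 9, 10), data$feature_ids)
  tr2 <- backward_eliminate(data, selection_config(evaluator = score_by_ids(w)))
  expect_identical(sort(tr2$iterations[[1]]$best_removed), data$feature_ids[1:2])
  expect_length(tr2$iterations[[1]]$next_surviving, 6)
})

test_that("majority-class contract: flat scores drive pure tie shrinkage", {
  syn <- generate_profiles(synthetic_spec(n_per_class = c(10, 14),
                                          n_features = 6, n_informative = 2, seed = 3))
  cfg <- selection_config(classifier = make_baseline("majority"), folds = 2, seed = 1)
  tr <- backward_eliminate(syn$profiles, cfg)
  expect_length(tr$iterations, 1)
  expect_length(unique(tr$iterations[[1]]$scores), 1L)
})

test_that("min_features bounds the surviving set and M < 2 errors", {
  data <- toy_profiles(n_per_class = 3, m = 10)
  w <- stats::setNames(seq_len(10), data$feature_ids)
  tr <- backward_eliminate(data, selection_config(evaluator = score_by_ids(w),
                                                  min_features = 4))
  expect_length(tr$final_survivors, 4)
  expect_error(backward_eliminate(data[, 1], selection_config()), "at least 2 features")
})

test_that("select_features picks the best-scoring iteration's survivors", {
  fake <- structure(list(
    iterations = list(
      list(surviving = letters[1:5], best_score = 0.7, next_surviving = letters[1:4]),
      list(surviving = letters[1:4], best_score = 0.9, next_surviving = letters[1:3]),
      list(surviving = letters[1:3], best_score = 0.8, next_surviving = letters[1:2])
    ),
    importance = c(e = 1L, d = 2L, c = 3L),
    final_survivors = letters[1:2]), class = "elimination_trace")
  expect_identical(select_features(fake), letters[1:3])
  # all-tie case: smallest (latest) surviving set wins
  for (i in 1:3) fake$iterations[[i]]$best_score <- 0.5
  expect_identical(select_features(fake), letters[1:2])
  empty <- structure(list(iterations = list(), importance = integer(0),
                          final_survivors = character(0)),
                     class = "elimination_trace")
  expect_error(select_features(empty), "empty")
})

test_that("evaluator failures carry iteration context", {
  data <- toy_profiles(n_per_class = 3, m = 5)
  boom <- function(d) stop("backend exploded")
  expect_error(backward_eliminate(data, selection_config(evaluator = boom)),
               "iteration 1.*backend exploded")
})

test_that("identical data, config and seed reproduce the trace exactly", {
  syn <- generate_profiles(synthetic_spec(n_per_class = c(10, 10),
                                          n_features = 8, n_informative = 3, seed = 5))
  cfg <- selection_config(
    classifier = hdc_classifier(encoding_config(300, 10, value_min = 0,
                                                value_max = 100, seed = 2)),
    folds = 2, seed = 9)
  expect_identical(backward_eliminate(syn$profiles, cfg),
                   backward_eliminate(syn$profiles, cfg))
})

test_that("trace export writes the documented TSV columns", {
  data <- toy_profiles(n_per_class = 3, m = 6)
  w <- stats::setNames(seq_len(6), data$feature_ids)
  tr <- backward_eliminate(data, selection_config(evaluator = score_by_ids(w)))
  path <- withr::local_tempfile(fileext = ".tsv")
  imp_path <- withr::local_tempfile(fileext = ".tsv")
  write_elimination_trace(tr, path, importance_path = imp_path)
  tab <- read.delim(path)
  expect_identical(names(tab),
                   c("iteration", "removed_feature", "score", "is_best", "surviving_count"))
  expect_identical(nrow(tab), sum(lengths(lapply(tr$iterations, `[[`, "scores"))))
  imp <- read.delim(imp_path)
  expect_setequal(imp$feature_id, data$feature_ids)
})
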