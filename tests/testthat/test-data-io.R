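write_lines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("well-formed tables round-trip through read/write, either orientation", {
  syn <- generate_profiles(synthetic_spec(n_per_class = c(3, 3),
                                          n_features = 4, n_informative = 2, seed = 8))
  path <- tempfile(fileext = ".tsv")
  write_abundance_table(syn$profiles, path)
  back <- read_abundance_table(path)
  expect_equal(back$matrix, syn$profiles$matrix)
  expect_identical(back$sample_ids, syn$profiles$sample_ids)

  # feature-major file read with the transpose flag equals the direct read
  tpath <- tempfile(fileext = ".tsv")
  tm <- t(syn$profiles$matrix)
  df <- data.frame(feature_id = rownames(tm), tm, check.names = FALSE)
  write.table(df, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  back_t <- read_abundance_table(tpath, transpose = TRUE)
  expect_equal(back_t$matrix, back$matrix)
})

test_that("csv input and named labels are honored", {
  path <- write_lines(c("id,f1,f2", "s1,1.5,2", "s2,3,4.25"), ".csv")
  labs <- c(s2 = "b", s1 = "a")
  data <- read_abundance_table(path, labels = labs)
  expect_identical(data$labels, c("a", "b"))
  expect_equal(data$matrix["s2", "f2"], 4.25)
})

test_that("parse errors name the offending line and column", {
  ragged <- write_lines(c("id\tf1\tf2", "s1\t1\t2", "s2\t3"))
  expect_error(read_abundance_table(ragged), "ragged row at line 3")
  bad_cell <- write_lines(c("id\tf1\tf2", "s1\t1\tx7", "s2\t3\t4"))
  expect_error(read_abundance_table(bad_cell), "non-numeric cell 'x7' at line 2, column 'f2'")
  dup <- write_lines(c("id\tf1\tf2", "s1\t1\t2", "s1\t3\t4"))
  expect_error(read_abundance_table(dup), "duplicate row identifier 's1'")
})

make_catalog_fixture <- function(study_sizes, balances, category = "condition") {
  # build profiles + metadata with per-study sample counts and minority fractions
  total <- sum(study_sizes)
  x <- matrix(runif(total * 3, 0, 100), total, 3)
  ids <- sprintf("s%04d", seq_len(total))
  rownames(x) <- ids
  study <- rep(names(study_sizes), study_sizes)
  label <- unlist(lapply(seq_along(study_sizes), function(i) {
    n <- study_sizes[i]
    n_min <- round(balances[i] * n)
    rep(c("sick", "well"), c(n_min, n - n_min))
  }))
  meta <- data.frame(sample_id = ids, study_id = study, condition = label)
  list(profiles = labeled_profiles(x), metadata = meta)
}

test_that("assembly applies the n >= 100 and normalized-balance filters", {
  fx <- make_catalog_fixture(
    study_sizes = c(A = 120, B = 99, C = 100, D = 150, E = 150),
    balances = c(0.50, 0.45, 0.40, 0.10, 0.34))
  out <- assemble_datasets(fx$profiles, fx$metadata, "condition")
  cat <- out$catalog
  rownames(cat) <- cat$study
  # normalization spans all candidates (computed before any retention decision)
  expect_equal(cat["A", "balance_normalized"], 1.0)
  expect_equal(cat["D", "balance_normalized"], 0.0)
  expect_false(cat["B", "retained"])   # 99 samples: dropped by the strict < 100 rule
  expect_true(cat["C", "retained"])    # exactly 100 samples: retained
  expect_false(cat["D", "retained"])   # normalized 0.0 < 0.6
  expect_equal(cat["E", "balance_normalized"], 0.6, tolerance = 1e-12)
  expect_true(cat["E", "retained"])    # 0.6 boundary is inclusive
  expect_identical(out$datasets[["A"]]$labels[1], "sick")
})

test_that("non-binary categories are skipped with a warning, missing category errors", {
  fx <- make_catalog_fixture(c(A = 10, B = 10), c(0.5, 0.5))
  fx$metadata$condition[fx$metadata$study_id == "B"][1] <- "other"
  expect_warning(out <- assemble_datasets(fx$profiles, fx$metadata, "condition"),
                 "study 'B'.*not binary")
  expect_identical(out$catalog$study, "A")
  expect_error(assemble_datasets(fx$profiles, fx$metadata, "smoker"),
               "category 'smoker' absent")
})

test_that("model archives round-trip bit-exactly and preserve predictions", {
  syn <- generate_profiles(synthetic_spec(n_per_class = c(8, 8),
                                          n_features = 6, n_informative = 2, seed = 13))
  model <- hdc_fit(syn$profiles, small_config(d = 400, m = 12))
  model <- hdc_retrain(model, syn$profiles, max_iterations = 5)
  path <- tempfile(fileext = ".json.gz")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$class_vectors, model$class_vectors)
  expect_identical(back$level_set$levels, model$level_set$levels)
  expect_identical(back$feature_ids, model$feature_ids)
  expect_equal(back$retrain_history, model$retrain_history)
  expect_identical(predict(back, syn$profiles), predict(model, syn$profiles))
})

test_that("corrupt, truncated or mismatched archives fail loudly", {
  syn <- generate_profiles(synthetic_spec(n_per_class = c(4, 4),
                                          n_features = 4, n_informative = 2, seed = 14))
  model <- hdc_fit(syn$profiles, small_config(d = 100, m = 5))
  path <- tempfile(fileext = ".json.gz")
  save_model(model, path)

  raw <- readBin(path, "raw", file.size(path))
  trunc_path <- tempfile(fileext = ".json.gz")
  writeBin(raw[seq_len(length(raw) %/% 3)], trunc_path)
  expect_error(load_model(trunc_path), "corrupt|unreadable|archive")

  not_model <- tempfile(fileext = ".json.gz")
  con <- gzfile(not_model, "wb"); writeLines('{"format": "other"}', con); close(con)
  expect_error(load_model(not_model), "not a hdclassify-model archive")

  # requested config differing from the archive: archive wins with a warning
  expect_warning(back <- load_model(path, config = encoding_config(64, 4)),
                 "archive's configuration wins")
  expect_identical(back$config$dimensionality, 100L)
})
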