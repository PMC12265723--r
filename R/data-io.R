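# Readers/writers for abundance tables and metadata, study assembly with the
# balance-score filters, and model archiving.

infer_sep <- function(line, path) {
  if (grepl("\t", line)) "\t"
  else if (grepl(",", line)) ","
  else stop(sprintf("cannot infer delimiter of '%s' (no tab or comma in header)",
                    path), call. = FALSE)
}

#' Read an abundance table
#'
#' Parses a rectangular TSV/CSV with a header row and a leading ID column
#' into [labeled_profiles()]. Parsing is strict: ragged rows, non-numeric
#' cells and duplicate identifiers raise errors naming the offending
#' line/column. The delimiter is inferred from the header (tab wins over
#' comma).
#'
#' @param path file path.
#' @param transpose set `TRUE` for feature-major files (rows = taxa,
#'   columns = samples); the result is always samples x features.
#' @param labels optional label vector or named vector keyed by sample ID.
#' @return a `labeled_profiles` (unlabeled unless `labels` given).
#' @export
read_abundance_table <- function(path, transpose = FALSE, labels = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop(sprintf("'%s': need a header and at least one data row", path),
                               call. = FALSE)
  sep <- infer_sep(lines[1], path)
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("'%s': ragged row at line %d (%d fields, expected %d)",
                 path, bad, widths[bad], widths[1]), call. = FALSE)
  }
  header <- cells[[1]]
  col_ids <- header[-1]
  row_ids <- vapply(cells[-1], `[[`, character(1), 1L)
  if (anyDuplicated(row_ids)) {
    stop(sprintf("'%s': duplicate row identifier '%s'",
                 path, row_ids[duplicated(row_ids)][1]), call. = FALSE)
  }
  if (anyDuplicated(col_ids)) {
    stop(sprintf("'%s': duplicate column identifier '%s'",
                 path, col_ids[duplicated(col_ids)][1]), call. = FALSE)
  }
  n <- length(row_ids)
  m <- length(col_ids)
  mat <- matrix(NA_real_, n, m, dimnames = list(row_ids, col_ids))
  for (i in seq_len(n)) {
    raw <- cells[[i + 1L]][-1]
    vals <- suppressWarnings(as.numeric(raw))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1]
      stop(sprintf("'%s': non-numeric cell '%s' at line %d, column '%s'",
                   path, raw[j], i + 1L, col_ids[j]), call. = FALSE)
    }
    mat[i, ] <- vals
  }
  if (transpose) mat <- t(mat)
  if (!is.null(labels) && !is.null(names(labels))) {
    labels <- unname(labels[rownames(mat)])
  }
  labeled_profiles(mat, labels = labels)
}

#' Write an abundance table as TSV
#'
#' @param data a [labeled_profiles()] object.
#' @param path output path (samples x features, header + ID column).
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(data, path) {
  stopifnot(inherits(data, "labeled_profiles"))
  df <- data.frame(sample_id = data$sample_ids, data$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample-label TSV
#'
#' @param path TSV with columns `sample_id` and `label` (header required).
#' @return named character vector of labels keyed by sample ID.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop(sprintf("'%s': expected two columns (sample_id, label)", path),
                          call. = FALSE)
  stats::setNames(as.character(df[[2]]), df[[1]])
}

#' Assemble per-study binary datasets with balance filtering
#'
#' Builds one candidate dataset per study from a metadata table, labels its
#' samples by the chosen category column, and applies the two retention
#' filters: at least 100 samples (strict "less than 100" is dropped), and a
#' min-max-normalized balance score — computed across *all* candidates before
#' any retention decision — within `[0.6, 1.0]` inclusive. Candidates whose
#' category has other than two observed values are skipped with a warning.
#'
#' @param profiles a [labeled_profiles()] holding all samples (labels
#'   ignored).
#' @param metadata data.frame with columns `sample_id`, `study_id`, and one
#'   column per category; must cover every profile sample.
#' @param category name of the metadata column to classify on.
#' @return a `dataset_catalog`: `catalog` (data.frame with study, category,
#'   classes, n_samples, balance_raw, balance_normalized, retained) and
#'   `datasets` (named list of labeled `labeled_profiles`, one per candidate).
#' @export
assemble_datasets <- function(profiles, metadata, category) {
  stopifnot(inherits(profiles, "labeled_profiles"), is.data.frame(metadata))
  for (col in c("sample_id", "study_id")) {
    if (!col %in% names(metadata)) {
      stop(sprintf("metadata lacks required column '%s'", col), call. = FALSE)
    }
  }
  if (!category %in% names(metadata)) {
    stop(sprintf("category '%s' absent from metadata columns (%s)",
                 category, paste(setdiff(names(metadata), c("sample_id", "study_id")),
                                 collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(profiles$sample_ids, metadata$sample_id)
  if (length(missing)) {
    stop(sprintf("metadata does not cover %d sample(s), e.g. '%s'",
                 length(missing), missing[1]), call. = FALSE)
  }
  meta <- metadata[match(profiles$sample_ids, metadata$sample_id), ]

  studies <- unique(meta$study_id)
  entries <- list()
  datasets <- list()
  for (st in studies) {
    sel <- which(meta$study_id == st & !is.na(meta[[category]]))
    if (length(sel) == 0L) next
    labs <- as.character(meta[[category]][sel])
    classes <- sort(unique(labs))
    if (length(classes) != 2L) {
      warning(sprintf("study '%s': category '%s' has %d value(s), not binary; skipped",
                      st, category, length(classes)), call. = FALSE)
      next
    }
    d <- profiles[sel, ]
    d$labels <- labs
    datasets[[st]] <- d
    entries[[st]] <- data.frame(
      study = st, category = category,
      classes = paste(classes, collapse = "|"),
      n_samples = length(sel),
      balance_raw = balance_score(labs),
      stringsAsFactors = FALSE)
  }
  if (length(entries) == 0L) {
    stop(sprintf("no binary candidate datasets for category '%s'", category),
         call. = FALSE)
  }
  catalog <- do.call(rbind, entries)
  rownames(catalog) <- NULL
  catalog$balance_normalized <- if (nrow(catalog) >= 2 &&
                                    max(catalog$balance_raw) > min(catalog$balance_raw)) {
    normalize_scores(catalog$balance_raw)
  } else {
    rep(1.0, nrow(catalog))  # a single candidate (or all-equal scores) is trivially at the max
  }
  # inclusive balance window [0.6, 1.0]; 1e-9 slack keeps boundary candidates
  # from falling to floating-point representation of the score ratios
  catalog$retained <- catalog$n_samples >= 100 &
    catalog$balance_normalized >= 0.6 - 1e-9 &
    catalog$balance_normalized <= 1.0 + 1e-9
  structure(list(catalog = catalog, datasets = datasets), class = "dataset_catalog")
}

#' @export
print.dataset_catalog <- function(x, ...) {
  cat(sprintf("<dataset_catalog> %d candidate(s), %d retained\n",
              nrow(x$catalog), sum(x$catalog$retained)))
  print(x$catalog)
  invisible(x)
}

MODEL_FORMAT <- "hdclassify-model"
MODEL_FORMAT_VERSION <- 1L

#' Save an HDC model archive
#'
#' Serializes the full model (config, level vectors, class vectors, feature
#' IDs) plus training provenance as gzipped JSON. All entries are integers,
#' so the round trip [load_model()] is bit-exact.
#'
#' @param model an `hdc_model`.
#' @param path output path (conventionally `.json.gz`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hdc_model"))
  payload <- list(
    format = MODEL_FORMAT,
    version = MODEL_FORMAT_VERSION,
    config = list(dimensionality = model$config$dimensionality,
                  levels = model$config$levels,
                  value_min = model$config$value_min,
                  value_max = model$config$value_max,
                  seed = model$config$seed),
    classes = rownames(model$class_vectors),
    class_vectors = unname(apply(model$class_vectors, 1, as.integer, simplify = FALSE)),
    level_vectors = unname(apply(model$level_set$levels, 1, as.integer, simplify = FALSE)),
    feature_ids = model$feature_ids,
    retrain_history = model$retrain_history,
    accepted_iteration = if (is.na(model$accepted_iteration)) NULL else model$accepted_iteration,
    provenance = list(package_version = as.character(utils::packageVersion("hdclassify")),
                      saved_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null"),
             con)
  invisible(path)
}

#' Load an HDC model archive
#'
#' @param path archive written by [save_model()].
#' @param config optional requested [encoding_config()]; on mismatch the
#'   archive's stored configuration wins with a warning (provenance
#'   precedence).
#' @return the restored `hdc_model`, bit-identical to the saved one.
#' @export
load_model <- function(path, config = NULL) {
  payload <- tryCatch({
    con <- gzfile(path, "rb")
    on.exit(close(con))
    jsonlite::fromJSON(paste(readLines(con, warn = FALSE), collapse = "\n"),
                       simplifyVector = TRUE)
  }, error = function(e) {
    stop(sprintf("corrupt or unreadable model archive '%s': %s",
                 path, conditionMessage(e)), call. = FALSE)
  })
  if (!identical(payload$format, MODEL_FORMAT)) {
    stop(sprintf("'%s' is not a %s archive", path, MODEL_FORMAT), call. = FALSE)
  }
  if (!identical(as.integer(payload$version), MODEL_FORMAT_VERSION)) {
    stop(sprintf("unsupported model archive version %s (supported: %d)",
                 payload$version, MODEL_FORMAT_VERSION), call. = FALSE)
  }
  stored <- encoding_config(payload$config$dimensionality, payload$config$levels,
                            payload$config$value_min, payload$config$value_max,
                            seed = payload$config$seed)
  if (!is.null(config) && !identical(unclass(config)[c("dimensionality", "levels")],
                                     unclass(stored)[c("dimensionality", "levels")])) {
    warning("requested encoding configuration differs from the archive; the archive's configuration wins",
            call. = FALSE)
  }
  lv <- payload$level_vectors
  if (!is.matrix(lv)) lv <- do.call(rbind, lv)
  if (!is.matrix(lv)) stop("malformed model archive: level vectors", call. = FALSE)
  storage.mode(lv) <- "integer"
  cv <- payload$class_vectors
  if (!is.matrix(cv)) cv <- do.call(rbind, cv)
  storage.mode(cv) <- "double"
  rownames(cv) <- payload$classes
  level_set <- new_level_set(list(levels = lv, levels_t = t(lv)), stored)
  structure(list(class_vectors = cv, level_set = level_set, config = stored,
                 feature_ids = as.character(payload$feature_ids),
                 n_features = length(payload$feature_ids),
                 retrain_history = as.numeric(payload$retrain_history),
                 accepted_iteration = if (is.numeric(payload$accepted_iteration)) {
                   as.integer(payload$accepted_iteration)
                 } else NA_integer_),
            class = "hdc_model")
}
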