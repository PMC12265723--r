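# Synthetic compositional abundance profiles with known ground truth. The
# generative model is deliberately simple: per-feature log-normal abundances,
# a log-scale mean shift on a random subset of "informative" taxa in one
# class, independent zero-inflation (sparsity), and closure of every row to a
# constant total — reproducing the sparse, compositional, heavy-tailed shape
# of relative-abundance tables without claiming to match any real profiler's
# marginals.

#' Specification for the synthetic abundance generator
#'
#' @param n_per_class integer vector of per-class sample counts (length 2).
#' @param n_features number of taxa features `M`.
#' @param n_informative number of class-informative features (`<= M`).
#' @param effect log-scale mean shift added to informative features in the
#'   first class (default 2.0; must be `>= 0`).
#' @param sparsity zero-inflation probability in `[0, 1)` (default 0.3).
#' @param dispersion log-scale standard deviation (default 1.0, `> 0`).
#' @param total constant row sum after closure (default 100, the
#'   relative-abundance percentage scale).
#' @param class_labels two distinct labels; the first is the shifted class.
#' @param seed integer seed.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = c(100, 100), n_features = 50,
                           n_informative = 10, effect = 2, sparsity = 0.3,
                           dispersion = 1, total = 100,
                           class_labels = c("case", "control"), seed = 1) {
  stopifnot(length(n_per_class) == 2L, all(n_per_class >= 1),
            length(class_labels) == 2L, class_labels[1] != class_labels[2])
  assert_count(n_features, "n_features", min = 1)
  if (n_informative < 0 || n_informative > n_features) {
    stop("`n_informative` must be in [0, n_features]", call. = FALSE)
  }
  if (!is.finite(effect) || effect < 0) stop("`effect` must be >= 0", call. = FALSE)
  if (!is.finite(sparsity) || sparsity < 0 || sparsity >= 1) {
    stop("`sparsity` must be in [0, 1)", call. = FALSE)
  }
  if (!is.finite(dispersion) || dispersion <= 0) {
    stop("`dispersion` must be > 0", call. = FALSE)
  }
  if (!is.finite(total) || total <= 0) stop("`total` must be > 0", call. = FALSE)
  structure(list(n_per_class = as.integer(n_per_class),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect = effect, sparsity = sparsity, dispersion = dispersion,
                 total = total, class_labels = as.character(class_labels),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate labeled synthetic abundance profiles
#'
#' Draws log-abundances `Normal(0, dispersion)` per cell, adds `effect` to
#' the informative features (a random subset of positions, fixed by the seed)
#' for samples of the first class, exponentiates, zeroes cells independently
#' with probability `sparsity`, and closes each row to sum to `total`
#' (closure after zero-inflation, so zeros stay exact). Rows that would be
#' entirely zero have their zero mask redrawn.
#'
#' @param spec a [synthetic_spec()].
#' @return a `synthetic_profiles` list: `profiles` ([labeled_profiles()]),
#'   `informative_features` (ground-truth feature IDs), `spec`.
#' @export
#' @examples
#' syn <- generate_profiles(synthetic_spec(n_per_class = c(10, 10), seed = 1))
#' rowSums(syn$profiles$matrix)  # all 100
generate_profiles <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- sum(spec$n_per_class)
  m <- spec$n_features
  feature_ids <- sprintf("taxon_%03d", seq_len(m))
  sample_ids <- sprintf("S%04d", seq_len(n))
  labels <- rep(spec$class_labels, spec$n_per_class)

  out <- run_seeded(spec$seed, {
    informative <- sort(sample.int(m, spec$n_informative))
    logab <- matrix(stats::rnorm(n * m, mean = 0, sd = spec$dispersion), n, m)
    if (spec$n_informative > 0) {
      shifted <- labels == spec$class_labels[1]
      logab[shifted, informative] <- logab[shifted, informative] + spec$effect
    }
    ab <- exp(logab)
    keep <- matrix(stats::rbinom(n * m, 1L, 1 - spec$sparsity), n, m)
    for (i in which(rowSums(keep) == 0)) {
      while (sum(keep[i, ]) == 0) keep[i, ] <- stats::rbinom(m, 1L, 1 - spec$sparsity)
    }
    ab <- ab * keep
    ab <- ab / rowSums(ab) * spec$total
    list(ab = ab, informative = informative)
  })

  profiles <- labeled_profiles(out$ab, labels = labels,
                               sample_ids = sample_ids, feature_ids = feature_ids)
  structure(list(profiles = profiles,
                 informative_features = feature_ids[out$informative],
                 spec = spec),
            class = "synthetic_profiles")
}

#' @export
print.synthetic_profiles <- function(x, ...) {
  print(x$profiles)
  cat(sprintf("  informative: %s\n", paste(x$informative_features, collapse = ", ")))
  invisible(x)
}

#' Generate class-imbalanced synthetic profiles
#'
#' Same generative model as [generate_profiles()], with class sizes
#' `ceiling(minority_fraction * n_total)` (the shifted first class) versus
#' the rest, where `n_total` is the spec's total sample count.
#'
#' @param spec a [synthetic_spec()].
#' @param minority_fraction minority-class fraction in `(0, 0.5]`.
#' @return a `synthetic_profiles` list.
#' @export
generate_imbalanced <- function(spec, minority_fraction) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.numeric(minority_fraction) || length(minority_fraction) != 1L ||
      !is.finite(minority_fraction) ||
      minority_fraction <= 0 || minority_fraction > 0.5) {
    stop("`minority_fraction` must be in (0, 0.5]", call. = FALSE)
  }
  n_total <- sum(spec$n_per_class)
  n_min <- as.integer(ceiling(minority_fraction * n_total))
  spec$n_per_class <- c(n_min, n_total - n_min)
  generate_profiles(spec)
}

#' Write synthetic profiles in the package's TSV dialect
#'
#' Writes the abundance table (samples x features, via
#' [write_abundance_table()]), a two-column labels TSV, and a ground-truth
#' sidecar TSV (`feature_id`, `informative` flag).
#'
#' @param syn a `synthetic_profiles` object.
#' @param prefix output path prefix; files are `<prefix>_abundance.tsv`,
#'   `<prefix>_labels.tsv`, `<prefix>_truth.tsv`.
#' @return named character vector of the three paths, invisibly.
#' @export
write_profiles <- function(syn, prefix) {
  stopifnot(inherits(syn, "synthetic_profiles"))
  paths <- c(abundance = paste0(prefix, "_abundance.tsv"),
             labels = paste0(prefix, "_labels.tsv"),
             truth = paste0(prefix, "_truth.tsv"))
  write_abundance_table(syn$profiles, paths[["abundance"]])
  utils::write.table(
    data.frame(sample_id = syn$profiles$sample_ids, label = syn$profiles$labels),
    paths[["labels"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(feature_id = syn$profiles$feature_ids,
               informative = as.integer(
                 syn$profiles$feature_ids %in% syn$informative_features)),
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
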