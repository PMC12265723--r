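# Level-hypervector quantization: a numeric range is cut into m bins, each bin
# owning a bipolar hypervector. Bin 1 is a fresh random vector; walking up the
# bins flips a cumulative total of floor(D/2) fixed positions, spread evenly
# across the m-1 steps and never re-flipping a position. Nearby bins therefore
# stay similar (similarity gradient) while the first and last bins end up
# quasi-orthogonal — exactly the geometry needed to discriminate distant
# abundances but keep adjacent ones close.

# level matrices depend only on (D, m, seed); memoized so refitting across CV
# folds and elimination candidates does not redraw the same 10^6-entry matrix
.level_cache <- new.env(parent = emptyenv())

#' Encoding configuration
#'
#' Collects the free parameters of the level-vector encoding.
#'
#' @param dimensionality hypervector dimension `D` (default 10,000).
#' @param levels number of quantization levels `m` (default 100, i.e. unit-wide
#'   bins on a 0–100 relative-abundance scale).
#' @param value_min,value_max quantization range. The defaults (`NULL`) mean
#'   "resolve from the training data" at fit time; the resolved range is
#'   stored in the model so test data are quantized on the training scale.
#' @param seed integer seed governing the level-vector construction.
#' @return an `encoding_config` object.
#' @export
#' @examples
#' encoding_config(dimensionality = 1000, levels = 10, value_min = 0, value_max = 100)
encoding_config <- function(dimensionality = 10000, levels = 100,
                            value_min = NULL, value_max = NULL, seed = 1) {
  d <- assert_count(dimensionality, "dimensionality", min = 2)
  m <- assert_count(levels, "levels", min = 2)
  if (!is.null(value_min) || !is.null(value_max)) {
    if (is.null(value_min) || is.null(value_max)) {
      stop("supply both `value_min` and `value_max`, or neither", call. = FALSE)
    }
    if (!is.finite(value_min) || !is.finite(value_max) || value_max <= value_min) {
      stop("`value_max` must be finite and > `value_min`", call. = FALSE)
    }
  }
  structure(list(dimensionality = d, levels = m,
                 value_min = value_min, value_max = value_max,
                 seed = as.integer(seed)),
            class = "encoding_config")
}

resolve_encoding_range <- function(config, x) {
  if (!is.null(config$value_min)) return(config)
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo) {
    stop("cannot resolve quantization range: data values are all equal", call. = FALSE)
  }
  config$value_min <- lo
  config$value_max <- hi
  config
}

#' Build the ordered family of level hypervectors
#'
#' Level 1 is a fresh random bipolar vector. Each subsequent level flips a
#' fixed share of a `floor(D/2)` total flip budget, spread as evenly as
#' possible over the `m - 1` steps (remainder to the earliest steps), with
#' flip positions drawn once without replacement — so no position is ever
#' flipped twice. Consequences, exact by the flip-distance identity
#' \eqn{\cos = (D - 2f)/D}: adjacent levels are highly similar, similarity
#' decays linearly with level distance, and the first and last levels are
#' quasi-orthogonal (exactly orthogonal when `D` is even).
#'
#' @param config an [encoding_config()] with a resolved (non-`NULL`) range.
#' @return a `level_set`: list with `levels` (an `m x D` integer matrix),
#'   `m`, `d`, `value_min`, `value_max`, `seed`.
#' @export
#' @examples
#' ls <- build_level_vectors(encoding_config(1000, 10, 0, 100, seed = 3))
#' hv_cosine(ls$levels[1, ], ls$levels[10, ])  # ~0: ends quasi-orthogonal
build_level_vectors <- function(config) {
  stopifnot(inherits(config, "encoding_config"))
  if (is.null(config$value_min)) {
    stop("encoding range unresolved: set `value_min`/`value_max` or fit on data",
         call. = FALSE)
  }
  d <- config$dimensionality
  m <- config$levels
  total_flips <- d %/% 2L
  steps <- m - 1L
  if (steps > total_flips) {
    stop(sprintf("too many levels: m = %d needs more flip positions than floor(D/2) = %d",
                 m, total_flips), call. = FALSE)
  }
  seed <- config$seed
  cache_key <- sprintf("d%d_m%d_s%d", d, m, seed)
  if (!is.null(.level_cache[[cache_key]])) {
    return(new_level_set(.level_cache[[cache_key]], config))
  }
  lv <- run_seeded(seed, {
    base <- sample(c(-1L, 1L), d, replace = TRUE)
    flip_order <- sample.int(d, total_flips)
    per_step <- rep(total_flips %/% steps, steps)
    rem <- total_flips %% steps
    if (rem > 0) per_step[seq_len(rem)] <- per_step[seq_len(rem)] + 1L
    levels <- matrix(0L, nrow = m, ncol = d)
    levels[1L, ] <- base
    done <- 0L
    for (s in seq_len(steps)) {
      v <- levels[s, ]
      pos <- flip_order[(done + 1L):(done + per_step[s])]
      v[pos] <- -v[pos]
      levels[s + 1L, ] <- v
      done <- done + per_step[s]
    }
    levels
  })
  if (length(.level_cache) > 16L) rm(list = ls(.level_cache), envir = .level_cache)
  .level_cache[[cache_key]] <- list(levels = lv, levels_t = t(lv))
  new_level_set(.level_cache[[cache_key]], config)
}

# assemble a level_set from the (levels, levels_t) pair plus a config's range;
# levels_t is kept alongside for the contiguous access pattern of the encoder
new_level_set <- function(pair, config) {
  structure(list(levels = pair$levels, levels_t = pair$levels_t,
                 m = config$levels, d = config$dimensionality,
                 value_min = config$value_min, value_max = config$value_max,
                 seed = as.integer(config$seed)),
            class = "level_set")
}

#' @export
print.level_set <- function(x, ...) {
  cat(sprintf("<level_set> m = %d levels, D = %d, range [%g, %g]\n",
              x$m, x$d, x$value_min, x$value_max))
  invisible(x)
}

#' Map numeric values to level indices
#'
#' The quantization rule is `floor((x - value_min) / (value_max - value_min) * m)`
#' clamped into the valid bins, with `x = value_max` assigned to the last bin.
#' Values outside the range (possible for unseen test samples) are clamped to
#' the nearest boundary bin with a warning rather than rejected.
#'
#' @param x numeric vector of finite values.
#' @param level_set a [build_level_vectors()] result.
#' @return integer level indices in `[1, m]` (R's 1-based bin numbering).
#' @export
value_to_level <- function(x, level_set) {
  stopifnot(inherits(level_set, "level_set"))
  if (anyNA(x) || any(!is.finite(x))) {
    stop("non-finite values cannot be quantized", call. = FALSE)
  }
  lo <- level_set$value_min
  hi <- level_set$value_max
  if (any(x < lo) || any(x > hi)) {
    warning(sprintf("%d value(s) outside the quantization range [%g, %g] were clamped",
                    sum(x < lo | x > hi), lo, hi), call. = FALSE)
  }
  idx <- floor((x - lo) / (hi - lo) * level_set$m)
  idx <- pmin(pmax(idx, 0), level_set$m - 1L)
  as.integer(idx) + 1L
}

#' Encode a matrix of profiles into sample hypervectors
#'
#' Each sample row becomes the bundle of its features' level vectors, each
#' rotated by the (1-based) feature position minus one:
#' \deqn{S = \sum_{j=1}^{M} \rho^{\,j-1}\, L(x_j)}
#' The rotation ties every value to the feature slot it came from, so the
#' superposition keeps features distinguishable. The result is exact integer
#' arithmetic and independent of evaluation order.
#'
#' @param x numeric samples-by-features matrix.
#' @param level_set a [build_level_vectors()] result.
#' @return an `N x D` integer matrix of sample hypervectors.
#' @export
encode_profiles <- function(x, level_set) {
  stopifnot(is.matrix(x), inherits(level_set, "level_set"))
  if (ncol(x) < 1L) stop("cannot encode an empty feature set", call. = FALSE)
  lev <- matrix(value_to_level(as.numeric(x), level_set),
                nrow = nrow(x), ncol = ncol(x))
  encode_profiles_cpp(lev, level_set$levels_t %||% t(level_set$levels))
}

#' Encode one sample's feature vector
#'
#' @param values ordered numeric feature vector (length `M >= 1`).
#' @param level_set a [build_level_vectors()] result.
#' @return an integer hypervector of dimension `D`.
#' @export
#' @examples
#' ls <- build_level_vectors(encoding_config(500, 10, 0, 100, seed = 1))
#' s <- encode_sample(c(3.2, 50, 99.9), ls)
encode_sample <- function(values, level_set) {
  if (length(values) < 1L) stop("cannot encode an empty feature vector", call. = FALSE)
  drop(encode_profiles(matrix(as.numeric(values), nrow = 1L), level_set))
}
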