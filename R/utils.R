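`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random number generator seeded to `seed`, then
#' restores the caller's RNG state so library code never disturbs user-level
#' random streams. With `seed = NULL` the expression runs against the current
#' stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
run_seeded <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a child seed from a global seed and a purpose label
#'
#' Fans a single run-level seed out into independent per-component seeds so
#' that adding one pipeline stage never shifts another stage's random stream.
#' The derivation is a deterministic polynomial hash of the label added to the
#' parent seed, reduced modulo a prime below 2^31.
#'
#' @param seed integer parent seed.
#' @param what character label naming the consumer (e.g. `"cv"`, `"folds"`).
#' @return an integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' derive_seed(1, "cv")
derive_seed <- function(seed, what) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(what))
  h <- 0
  for (ch in utf8ToInt(what)) h <- (h * 31 + ch) %% 1000000007
  as.integer((abs(seed) + h) %% 2147483647)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
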