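# MAP-model (Multiply-Add-Permute) hypervector algebra. Hypervectors are plain
# R integer/numeric vectors: atomic vectors are bipolar (+1/-1), aggregates
# produced by bundling keep exact integer entries (no clipping), which is what
# makes the retraining subtractions reversible.

check_same_dim <- function(a, b) {
  if (length(a) != length(b)) {
    stop(sprintf("hypervector dimension mismatch: %d vs %d", length(a), length(b)),
         call. = FALSE)
  }
}

#' Generate a random bipolar hypervector
#'
#' Draws an atomic hypervector with independent entries, each \eqn{-1} or
#' \eqn{+1} with probability 1/2. In high dimension (default elsewhere in the
#' package is \eqn{D = 10{,}000}) two independent draws are quasi-orthogonal:
#' their cosine similarity has mean 0 and standard deviation \eqn{1/\sqrt{D}}.
#'
#' @param d dimensionality, an integer \eqn{\ge 2}.
#' @param seed optional integer seed; when supplied the draw is deterministic
#'   and the caller's RNG state is untouched.
#' @return an integer vector of length `d` with entries in `{-1, 1}`.
#' @export
#' @examples
#' a <- hv_random(16, seed = 7)
#' identical(a, hv_random(16, seed = 7))
hv_random <- function(d, seed = NULL) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d != round(d) || d < 2) {
    stop("invalid dimension: `d` must be a single integer >= 2", call. = FALSE)
  }
  run_seeded(seed, sample(c(-1L, 1L), as.integer(d), replace = TRUE))
}

#' Bundle (element-wise add) two hypervectors
#'
#' Bundling superposes its inputs: the result keeps a high cosine similarity
#' to every summand (1/\eqn{\sqrt 2} for two independent bipolar inputs).
#' Integer addition makes bundling exactly commutative and associative, so a
#' class hypervector is independent of the order its samples arrive in.
#'
#' @param a,b hypervectors of equal dimension.
#' @return the element-wise sum.
#' @export
hv_bundle <- function(a, b) {
  check_same_dim(a, b)
  a + b
}

#' Bind (element-wise multiply) two hypervectors
#'
#' Binding forms a new association quasi-orthogonal to both inputs. For
#' bipolar vectors it is self-inverse: `hv_bind(hv_bind(a, b), b)` recovers
#' `a` exactly, and it distributes over bundling.
#'
#' @param a,b hypervectors of equal dimension.
#' @return the element-wise product.
#' @export
hv_bind <- function(a, b) {
  check_same_dim(a, b)
  a * b
}

#' Permute (circularly rotate) a hypervector
#'
#' Rotates the coordinate sequence by `k` positions toward higher indices
#' (`k` is taken modulo the dimension). Rotation is norm-preserving,
#' invertible (`hv_permute(hv_permute(a, k), d - k)` is `a`), distributes
#' over both bundling and binding, and sends a random vector to a
#' quasi-orthogonal one — which is what encodes feature position.
#'
#' @param a a hypervector.
#' @param k non-negative integer rotation.
#' @return the rotated vector.
#' @export
hv_permute <- function(a, k) {
  d <- length(a)
  k <- as.integer(k %% d)
  if (k == 0L) return(a)
  a[c((d - k + 1L):d, 1L:(d - k))]
}

#' Cosine similarity between two hypervectors
#'
#' @param a,b hypervectors of equal dimension.
#' @return `sum(a*b) / (|a| |b|)` in `[-1, 1]`; 0 when either vector is
#'   all-zero (a class vector can pass through zero during retraining, and
#'   "maximally non-matching" is the safe reading).
#' @export
hv_cosine <- function(a, b) {
  check_same_dim(a, b)
  a <- as.numeric(a)
  b <- as.numeric(b)
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
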