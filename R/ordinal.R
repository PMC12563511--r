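# Ordinal-pattern primitives: amplitude permutations with the minimum-rank
# tie rule, forward/backward pattern distributions, permutation entropy and
# the permutation time irreversibility index (PTIRR).

#' Amplitude permutation of a numeric vector
#'
#' Encodes the ordinal structure of a vector as the tuple
#' `(j1, ..., jm)` where `ji` is the position that the i-th original
#' element takes in the stably ascending-sorted vector. Tied elements are
#' kept in order of appearance and all members of a tie group share the
#' group's minimum position, so for exact ties the result equals
#' `rank(x, ties.method = "min")`.
#'
#' @param x Numeric vector of length `m >= 2`; all entries must be finite.
#' @param tie_tol Nonnegative absolute tolerance below which two values are
#'   considered tied. The default `0` uses exact floating-point equality;
#'   a positive tolerance treats `|x_i - x_j| <= tie_tol` as a tie,
#'   decided pairwise (useful for coarsely quantized data).
#' @return Integer vector of the same length as `x`: the amplitude
#'   permutation. Each entry lies in `1..m`; tie-free vectors yield a true
#'   permutation of `1..m`.
#' @examples
#' amplitude_permutation(c(4, 7, 2))  # 2 3 1
#' amplitude_permutation(c(5, 5, 3))  # 2 2 1 (tied values share rank 2)
#' @seealso [backward_permutation()], [pattern_distribution()]
#' @export
amplitude_permutation <- function(x, tie_tol = 0) {
  x <- as.numeric(x)
  m <- length(x)
  if (m < 2L)
    stop("`x` must have at least 2 entries; a 1-tuple has no ordinal structure")
  if (!all(is.finite(x)))
    stop("`x` contains non-finite values; amplitude permutations require finite input")
  if (!is.numeric(tie_tol) || length(tie_tol) != 1L || is.na(tie_tol) || tie_tol < 0)
    stop("`tie_tol` must be a single nonnegative number")
  if (tie_tol == 0) {
    as.integer(rank(x, ties.method = "min"))
  } else {
    # minimum rank = 1 + number of elements strictly below the tie band
    vapply(seq_len(m), function(i) 1L + sum(x < x[i] - tie_tol), integer(1))
  }
}

#' Backward (time-reversed) permutation
#'
#' The amplitude permutation of the time-reversed vector. Because the
#' minimum-rank tie rule depends only on the multiset of values, this is
#' exactly the tuple reversal of the forward permutation, which is how it
#' is computed.
#'
#' @param forward Integer vector: a valid amplitude permutation.
#' @return The backward permutation (integer vector).
#' @examples
#' backward_permutation(c(2L, 3L, 1L))  # 1 3 2
#' @export
backward_permutation <- function(forward) {
  .check_permutation(forward)
  rev(as.integer(forward))
}

.check_permutation <- function(p) {
  p <- as.integer(p)
  m <- length(p)
  if (m < 2L || anyNA(p) || any(p < 1L) || any(p > m))
    stop("not a valid amplitude permutation: entries must be integers in 1..m, m >= 2")
  invisible(p)
}

# ---- internal pattern coding ------------------------------------------------

# Embedding vectors are mapped to integer codes in 0..(m^m - 1): the rank
# tuple (j1,...,jm) becomes sum_i (j_i - 1) * m^(i-1). Ranks are computed
# vectorised over all vectors as minimum ranks (1 + count of strictly
# smaller coordinates), which is the tie rule above.
.ordinal_codes <- function(x, m, tau, tie_tol = 0) {
  l <- length(x)
  n <- l - (m - 1L) * tau
  if (n < 1L)
    stop(sprintf(
      "series too short for one embedding vector: length %d < minimum %d (m = %d, tau = %d)",
      l, (m - 1L) * tau + 1L, m, tau))
  idx <- outer(seq_len(n), (seq_len(m) - 1L) * tau, "+")
  X <- matrix(x[idx], nrow = n, ncol = m)
  R <- matrix(1L, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      if (k != j) R[, j] <- R[, j] + (X[, k] < X[, j] - tie_tol)
    }
  }
  pow <- m^(seq_len(m) - 1L)
  as.integer((R - 1L) %*% pow)
}

.decode_pattern <- function(code, m) {
  out <- integer(m)
  for (i in seq_len(m)) {
    out[i] <- code %% m + 1L
    code <- code %/% m
  }
  out
}

.encode_pattern <- function(ranks, m) {
  sum((as.integer(ranks) - 1L) * m^(seq_len(m) - 1L))
}

.reverse_codes <- function(codes, m) {
  vapply(codes, function(cd) .encode_pattern(rev(.decode_pattern(cd, m)), m),
         numeric(1))
}

.pattern_key <- function(ranks) paste(ranks, collapse = ",")

# ---- pattern distribution ---------------------------------------------------

#' Empirical forward ordinal-pattern distribution of a time series
#'
#' Slides a delay embedding of dimension `m` and delay `tau` over the
#' series, maps each embedding vector to its amplitude permutation and
#' tabulates the forward pattern probabilities. The bookkeeping needed by
#' the irreversibility index is attached: `U` is the number of distinct
#' observed forward patterns and `V` the number of distinct patterns that
#' occur either as a forward pattern or as the backward image (tuple
#' reversal) of one.
#'
#' Backward-pattern probabilities are not estimated by a second scan of the
#' reversed series: the backward permutation is a deterministic reversal of
#' the forward one, so `p(b(pi))` is read off as the forward probability of
#' the reversed tuple.
#'
#' @param x Numeric vector (the time series), all values finite.
#' @param m Embedding dimension (integer, `2 <= m <= 8`).
#' @param tau Embedding delay (integer `>= 1`).
#' @param tie_tol Tie tolerance passed to the rank rule; see
#'   [amplitude_permutation()].
#' @return An object of class `pattern_distribution`: a list with
#'   `patterns` (matrix, one observed pattern per row), `counts`, `prob`
#'   (both named by the comma-separated rank tuple), `n_vectors`, `U`, `V`,
#'   `m`, `tau`.
#' @examples
#' d <- pattern_distribution(c(1, 2, 3, 4, 5), m = 3, tau = 1)
#' d$prob   # the strictly increasing pattern "1,2,3" has probability 1
#' d$U; d$V # 1 observed forward pattern; its reversal makes V = 2
#' @export
pattern_distribution <- function(x, m = 3L, tau = 2L, tie_tol = 0) {
  x <- as.numeric(x)
  if (!all(is.finite(x)))
    stop("`x` contains non-finite values")
  m <- as.integer(m); tau <- as.integer(tau)
  if (is.na(m) || m < 2L || m > 8L)
    stop("`m` must be an integer in 2..8")
  if (is.na(tau) || tau < 1L)
    stop("`tau` must be a positive integer")
  codes <- .ordinal_codes(x, m, tau, tie_tol)
  n <- length(codes)
  tab <- tabulate(codes + 1L, nbins = m^m)
  obs <- which(tab > 0L) - 1L
  counts <- tab[obs + 1L]
  patterns <- t(vapply(obs, .decode_pattern, integer(m), m = m))
  keys <- apply(patterns, 1L, .pattern_key)
  names(counts) <- keys
  prob <- counts / n
  rev_obs <- .reverse_codes(obs, m)
  v_codes <- sort(unique(c(obs, rev_obs)))
  structure(list(
    patterns  = patterns,
    counts    = counts,
    prob      = prob,
    n_vectors = n,
    U         = length(obs),
    V         = length(v_codes),
    m         = m,
    tau       = tau,
    tie_tol   = tie_tol,
    codes     = obs,
    v_codes   = v_codes
  ), class = "pattern_distribution")
}

#' @export
print.pattern_distribution <- function(x, ...) {
  cat(sprintf("Ordinal pattern distribution (m = %d, tau = %d)\n", x$m, x$tau))
  cat(sprintf("  %d embedding vectors, U = %d forward patterns, V = %d\n",
              x$n_vectors, x$U, x$V))
  print(round(x$prob, 4))
  invisible(x)
}

#' Pattern counts as a named vector (e.g. for JSON serialization)
#'
#' @param dist A `pattern_distribution`.
#' @return Named integer vector of forward pattern counts, names are the
#'   comma-separated rank tuples. `jsonlite::toJSON(as.list(...))` gives a
#'   debuggable representation.
#' @export
pattern_counts <- function(dist) {
  stopifnot(inherits(dist, "pattern_distribution"))
  dist$counts
}

# ---- indices ----------------------------------------------------------------

#' Permutation entropy of a pattern distribution
#'
#' Shannon entropy of the forward ordinal-pattern probabilities,
#' `PE = -sum p log p` over the `U` observed patterns, with `0 log 0 := 0`.
#' Natural logarithm by default; the maximum for a tie-free series is
#' `log(factorial(m))`.
#'
#' @param dist A `pattern_distribution`.
#' @param base Logarithm base; `exp(1)` (default) or e.g. `2`.
#' @param normalized If `TRUE`, divide by `log(factorial(m))` (in the same
#'   base) so the tie-free maximum is 1.
#' @return Nonnegative scalar.
#' @examples
#' d <- pattern_distribution(rnorm(1000), m = 3, tau = 1)
#' permutation_entropy(d)                      # close to log(6)
#' permutation_entropy(d, normalized = TRUE)   # close to 1
#' @export
permutation_entropy <- function(dist, base = exp(1), normalized = FALSE) {
  stopifnot(inherits(dist, "pattern_distribution"))
  p <- dist$prob[dist$prob > 0]
  h <- -sum(p * log(p)) / log(base)
  if (normalized) h <- h / (lfactorial(dist$m) / log(base))
  h
}

#' Permutation time irreversibility index (PTIRR)
#'
#' Quantifies the statistical asymmetry of a series under time reversal
#' from its ordinal-pattern distribution:
#' `PTIRR = sum_k p(f_k) * |p(f_k) - p(b_k)| / (p(f_k) + p(b_k))`,
#' summed over the `V` patterns that occur as forward patterns or as
#' backward images of forward patterns, where `b_k` is the tuple reversal
#' of `f_k`. The index lies in `[0, 1]`: 0 for a pattern-symmetric
#' distribution (e.g. stationary linear Gaussian processes, in
#' expectation), 1 when no observed pattern's reversal is ever observed
#' (e.g. a strictly monotone ramp).
#'
#' Algebraically the sum collapses to
#' `sum over unordered pairs {pi, rev(pi)} of |p(pi) - p(rev(pi))|`,
#' with self-reverse patterns contributing zero.
#'
#' @param dist A `pattern_distribution`.
#' @return Scalar in `[0, 1]`.
#' @examples
#' permutation_time_irreversibility(pattern_distribution(1:50, m = 3, tau = 1)) # 1
#' @export
permutation_time_irreversibility <- function(dist) {
  stopifnot(inherits(dist, "pattern_distribution"))
  v <- dist$v_codes
  pf <- dist$prob[match(v, dist$codes)]
  pf[is.na(pf)] <- 0
  pb <- dist$prob[match(.reverse_codes(v, dist$m), dist$codes)]
  pb[is.na(pb)] <- 0
  # every code in V has pf > 0 or pb > 0, so the denominator never vanishes
  sum(pf * abs(pf - pb) / (pf + pb))
}
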