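# Embedding-parameter selection: false nearest neighbors (dimension) and
# the C-C correlation-integral method (delay), plus mode aggregation across
# channels. These selectors are advisory: the analysis defaults remain
# m = 3, tau = 2 without running them.

.delay_embed <- function(x, m, tau) {
  n <- length(x) - (m - 1L) * tau
  if (n < 2L)
    stop(sprintf("series too short for an m = %d, tau = %d embedding", m, tau))
  idx <- outer(seq_len(n), (seq_len(m) - 1L) * tau, "+")
  matrix(x[idx], nrow = n, ncol = m)
}

#' Embedding dimension by false nearest neighbors
#'
#' For each candidate dimension `m`, finds every embedded point's nearest
#' (Euclidean) neighbor and flags the pair as false neighbors when adding
#' the (m+1)-th coordinate separates them: either the added-coordinate
#' distance exceeds `r_tol` times the m-dimensional distance, or the
#' expanded distance exceeds `a_tol` times the standard deviation of the
#' series. The chosen dimension is the smallest `m` whose false-neighbor
#' fraction falls below `threshold`.
#'
#' Nearest-neighbor search is exact over at most `max_points` embedded
#' points (evenly subsampled beyond that) to bound the quadratic cost.
#'
#' @param x Numeric vector; must not be constant.
#' @param tau Embedding delay used during the search.
#' @param max_m Largest dimension examined.
#' @param r_tol Ratio criterion threshold (standard default 10).
#' @param a_tol Loneliness criterion threshold in units of the series
#'   standard deviation (standard default 2).
#' @param threshold False-neighbor fraction below which a dimension is
#'   accepted (default 0.01).
#' @param max_points Cap on the number of points used in the neighbor
#'   search (default 2000).
#' @return Object of class `fnn_result`: list with `fractions` (named by
#'   dimension), `chosen_m`, and `converged` (`FALSE` when no dimension
#'   reached the threshold, in which case `chosen_m = max_m`).
#' @examples
#' s <- sin(2 * pi * (1:800) / 40)
#' fnn_dimension(s, tau = 10, max_m = 5)$chosen_m  # 2: a circle embeds in the plane
#' @export
fnn_dimension <- function(x, tau = 1L, max_m = 8L, r_tol = 10, a_tol = 2,
                          threshold = 0.01, max_points = 2000L) {
  x <- as.numeric(x)
  tau <- as.integer(tau); max_m <- as.integer(max_m)
  if (tau < 1L || max_m < 1L) stop("`tau` and `max_m` must be positive integers")
  sd_x <- stats::sd(x)
  if (!is.finite(sd_x) || sd_x == 0)
    stop("degenerate (constant) series: nearest neighbors are undefined")
  if (length(x) < max_m * tau + 1L)
    stop(sprintf("series too short: need length > %d for max_m = %d, tau = %d",
                 max_m * tau, max_m, tau))
  fractions <- numeric(max_m)
  names(fractions) <- seq_len(max_m)
  for (m in seq_len(max_m)) {
    # points needing the (m+1)-th coordinate x[t + m*tau]
    n_valid <- length(x) - m * tau
    pts <- seq_len(n_valid)
    if (n_valid > max_points)
      pts <- unique(as.integer(round(seq(1L, n_valid, length.out = max_points))))
    Y <- .delay_embed(x, m, tau)[pts, , drop = FALSE]
    D <- as.matrix(stats::dist(Y))
    diag(D) <- Inf
    nn <- apply(D, 1L, which.min)
    rm_d <- D[cbind(seq_along(pts), nn)]
    extra <- abs(x[pts + m * tau] - x[pts[nn] + m * tau])
    # floor guards against exact state revisits, where rm_d and extra are
    # both at rounding-noise level and their ratio is meaningless
    floor_d <- 1e-8 * sd_x
    false_ratio <- extra > pmax(r_tol * rm_d, floor_d)
    false_lone  <- sqrt(rm_d^2 + extra^2) / sd_x > a_tol
    fractions[m] <- mean(false_ratio | false_lone)
  }
  ok <- which(fractions < threshold)
  structure(list(
    fractions = fractions,
    chosen_m  = if (length(ok)) as.integer(min(ok)) else max_m,
    converged = length(ok) > 0,
    threshold = threshold, r_tol = r_tol, a_tol = a_tol, tau = tau
  ), class = "fnn_result")
}

#' @export
print.fnn_result <- function(x, ...) {
  cat("False-nearest-neighbor fractions by dimension:\n")
  print(round(x$fractions, 4))
  cat(sprintf("chosen m = %d (%s)\n", x$chosen_m,
              if (x$converged) sprintf("fraction < %g", x$threshold)
              else "no dimension reached the threshold"))
  invisible(x)
}

# correlation integral of an embedded series (sup norm), one value per radius
.corr_integral <- function(Y, radii) {
  n <- nrow(Y)
  if (n < 2L) return(rep(NA_real_, length(radii)))
  d <- stats::dist(Y, method = "maximum")
  vapply(radii, function(r) mean(d < r), numeric(1))
}

#' Embedding delay by the C-C method
#'
#' Computes the correlation-integral statistic
#' `S(m, r, t) = mean over the t disjoint sub-series of
#' C_s(m, r, t) - C_s(1, r, t)^m` for each candidate delay `t`, dimensions
#' `m_set` and radii `radius_mult * sd(x)`, together with its spread over
#' radii `dS(m, t) = max_r S - min_r S`. The chosen delay is the first
#' local minimum of the radius-and-dimension-averaged `dS` curve; if no
#' local minimum occurs within `max_tau`, `max_tau` is returned with
#' `converged = FALSE`.
#'
#' @param x Numeric vector (a few hundred samples or more).
#' @param max_tau Largest delay examined (default 20).
#' @param m_set Embedding dimensions averaged over (standard 2..5).
#' @param radius_mult Radii as multiples of `sd(x)` (standard
#'   `c(0.5, 1, 1.5, 2)`).
#' @param max_points Cap on samples used (evenly thinned beyond it).
#' @return Object of class `cc_result`: list with `statistic` (data frame
#'   of `tau`, `S_mean`, `dS_mean`), `chosen_tau`, `converged`.
#' @examples
#' s <- sin(2 * pi * (1:1200) / 40)
#' cc_delay(s, max_tau = 20)$chosen_tau  # near a quarter period (10)
#' @export
cc_delay <- function(x, max_tau = 20L, m_set = 2:5,
                     radius_mult = c(0.5, 1, 1.5, 2), max_points = 1500L) {
  x <- as.numeric(x)
  max_tau <- as.integer(max_tau)
  n <- length(x)
  if (n < 300L)
    stop("series too short for the C-C method: need at least 300 samples")
  if (n > max_points)
    x <- x[unique(as.integer(round(seq(1, n, length.out = max_points))))]
  n <- length(x)
  sd_x <- stats::sd(x)
  if (sd_x == 0) stop("degenerate (constant) series")
  radii <- radius_mult * sd_x
  s_mean <- ds_mean <- numeric(max_tau)
  for (t in seq_len(max_tau)) {
    s_by_m <- matrix(NA_real_, nrow = length(m_set), ncol = length(radii))
    for (mi in seq_along(m_set)) {
      m <- m_set[mi]
      s_sub <- matrix(NA_real_, nrow = t, ncol = length(radii))
      for (sub in seq_len(t)) {
        xs <- x[seq(sub, n, by = t)]
        if (length(xs) < (m - 1L) * 1L + 2L) next
        c1 <- .corr_integral(matrix(xs, ncol = 1L), radii)
        if (length(xs) < m + 1L) next
        cm <- .corr_integral(.delay_embed(xs, m, 1L), radii)
        s_sub[sub, ] <- cm - c1^m
      }
      s_by_m[mi, ] <- colMeans(s_sub, na.rm = TRUE)
    }
    s_mean[t]  <- mean(s_by_m, na.rm = TRUE)
    ds_mean[t] <- mean(apply(s_by_m, 1L, function(v) max(v) - min(v)), na.rm = TRUE)
  }
  is_min <- which(diff(sign(diff(ds_mean))) > 0) + 1L
  structure(list(
    statistic  = data.frame(tau = seq_len(max_tau), S_mean = s_mean,
                            dS_mean = ds_mean),
    chosen_tau = if (length(is_min)) as.integer(min(is_min)) else max_tau,
    converged  = length(is_min) > 0
  ), class = "cc_result")
}

#' @export
print.cc_result <- function(x, ...) {
  cat(sprintf("C-C delay selection: chosen tau = %d%s\n", x$chosen_tau,
              if (x$converged) "" else " (no local minimum; max_tau returned)"))
  print(utils::head(round(x$statistic, 4), 10))
  invisible(x)
}

#' Aggregate per-channel parameter choices by their mode
#'
#' The study-level embedding parameters are the most frequent per-channel
#' choices; ties are broken toward the smaller (more conservative) value.
#'
#' @param choices Nonempty integer vector of per-channel choices.
#' @return The modal value (integer).
#' @examples
#' aggregate_by_mode(c(3, 3, 2, 3, 4))  # 3
#' aggregate_by_mode(c(2, 3, 2, 3))     # 2 (tie broken to the smaller)
#' @export
aggregate_by_mode <- function(choices) {
  choices <- as.integer(choices)
  if (length(choices) == 0L || anyNA(choices))
    stop("`choices` must be a nonempty integer vector without NAs")
  tab <- table(choices)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)
}
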