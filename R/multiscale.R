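# Coarse-graining and multiscale index profiles (MsPE / MsPTIRR).

#' Coarse-grain a series by non-overlapping window averaging
#'
#' At scale `s` the coarse-grained series is
#' `y(N) = mean(x[(s*(N-1)+1) : (s*N)])` for `N = 1 .. floor(l/s)`;
#' trailing samples beyond `s * floor(l/s)` are discarded. Scale 1
#' reproduces the input exactly.
#'
#' @param x Numeric vector.
#' @param scale Positive integer scale factor, at most `length(x)`.
#' @return Numeric vector of length `floor(length(x) / scale)`.
#' @examples
#' coarse_grain(1:6, 2)  # 1.5 3.5 5.5
#' @export
coarse_grain <- function(x, scale) {
  x <- as.numeric(x)
  scale <- as.integer(scale)
  if (is.na(scale) || scale < 1L)
    stop("`scale` must be a positive integer")
  l <- length(x)
  nw <- l %/% scale
  if (nw < 1L)
    stop(sprintf("scale %d exceeds series length %d: no complete window", scale, l))
  if (scale == 1L) return(x)
  colMeans(matrix(x[seq_len(nw * scale)], nrow = scale))
}

#' Single-scale ordinal index of a series
#'
#' Coarse-grains the series at the given scale, builds the ordinal-pattern
#' distribution and returns the requested index (PTIRR or PE). This is one
#' point of an MsPTIRR/MsPE profile.
#'
#' @param x Numeric vector.
#' @param scale Positive integer scale factor.
#' @param m,tau Embedding dimension and delay (defaults 3 and 2, the modes
#'   selected for resting MEG by FNN/C-C). The delay acts on the
#'   coarse-grained series.
#' @param kind `"PTIRR"` or `"PE"`.
#' @param tie_tol Tie tolerance; see [amplitude_permutation()].
#' @param ... Passed to [permutation_entropy()] (e.g. `normalized`).
#' @return Scalar index value.
#' @export
index_at_scale <- function(x, scale, m = 3L, tau = 2L,
                           kind = c("PTIRR", "PE"), tie_tol = 0, ...) {
  kind <- match.arg(kind)
  y <- coarse_grain(x, scale)
  dist <- tryCatch(
    pattern_distribution(y, m = m, tau = tau, tie_tol = tie_tol),
    error = function(e)
      stop(sprintf("at scale %d: %s", as.integer(scale), conditionMessage(e)),
           call. = FALSE))
  switch(kind,
         PTIRR = permutation_time_irreversibility(dist),
         PE    = permutation_entropy(dist, ...))
}

#' Largest feasible scale factor for a series
#'
#' The largest `s` such that the coarse-grained series still admits at
#' least one embedding vector, i.e. `floor(l/s) >= (m-1)*tau + 1`.
#'
#' @inheritParams index_at_scale
#' @export
max_feasible_scale <- function(x, m = 3L, tau = 2L) {
  length(x) %/% ((as.integer(m) - 1L) * as.integer(tau) + 1L)
}

#' Multiscale index profile (MsPTIRR / MsPE curve)
#'
#' Computes the requested ordinal index at each scale factor, giving the
#' multiscale permutation time irreversibility (MsPTIRR) or multiscale
#' permutation entropy (MsPE) profile of the series.
#'
#' @inheritParams index_at_scale
#' @param scales Strictly increasing integer vector of scale factors
#'   (default `1:100`).
#' @return A data frame of class `ms_profile` with columns `scale` and
#'   `value`, and attributes `kind`, `m`, `tau`.
#' @examples
#' pr <- ms_profile(rnorm(3000), scales = 1:10, kind = "PTIRR")
#' head(pr)
#' @export
ms_profile <- function(x, scales = 1:100, m = 3L, tau = 2L,
                       kind = c("PTIRR", "PE"), tie_tol = 0, ...) {
  kind <- match.arg(kind)
  scales <- as.integer(scales)
  if (anyNA(scales) || any(scales < 1L) || is.unsorted(scales, strictly = TRUE))
    stop("`scales` must be strictly increasing positive integers")
  smax <- max_feasible_scale(x, m, tau)
  if (any(scales > smax))
    stop(sprintf(
      "scales %s are infeasible for this series: largest feasible scale is %d",
      paste(scales[scales > smax], collapse = ", "), smax))
  vals <- vapply(scales, function(s)
    index_at_scale(x, s, m = m, tau = tau, kind = kind, tie_tol = tie_tol, ...),
    numeric(1))
  structure(data.frame(scale = scales, value = vals),
            kind = kind, m = m, tau = tau,
            class = c("ms_profile", "data.frame"))
}

#' Per-channel and channel-averaged multiscale profiles for one subject
#'
#' Computes an [ms_profile()] for every channel of a multichannel recording
#' and the unweighted cross-channel mean at each scale; the mean profile is
#' the subject-level MsPTIRR/MsPE index.
#'
#' @param recording Numeric matrix, channels in rows, samples in columns;
#'   row names are taken as channel labels.
#' @param channels Optional character or integer vector selecting a subset
#'   of channels (e.g. one brain region).
#' @param subject_id,group Optional labels carried through to the tidy
#'   representation.
#' @inheritParams ms_profile
#' @return An object of class `subject_profile`: a list with `values`
#'   (channels x scales matrix), `mean` (numeric, the channel-averaged
#'   profile), `scales`, `kind`, `m`, `tau`, `subject_id`, `group`. Use
#'   [as.data.frame.subject_profile()] for the tidy long form.
#' @export
subject_profile <- function(recording, scales = 1:100, m = 3L, tau = 2L,
                            kind = c("PTIRR", "PE"), channels = NULL,
                            subject_id = NA_character_, group = NA_character_,
                            tie_tol = 0) {
  kind <- match.arg(kind)
  if (!is.matrix(recording) || !is.numeric(recording))
    stop("`recording` must be a numeric matrix (channels x samples)")
  if (is.null(rownames(recording)))
    rownames(recording) <- sprintf("ch%03d", seq_len(nrow(recording)))
  if (!is.null(channels)) {
    if (is.character(channels) && !all(channels %in% rownames(recording)))
      stop("unknown channel labels: ",
           paste(setdiff(channels, rownames(recording)), collapse = ", "))
    recording <- recording[channels, , drop = FALSE]
  }
  if (nrow(recording) < 1L) stop("no channels selected")
  scales <- as.integer(scales)
  vals <- t(apply(recording, 1L, function(ch)
    ms_profile(ch, scales = scales, m = m, tau = tau, kind = kind,
               tie_tol = tie_tol)$value))
  if (length(scales) == 1L) vals <- matrix(vals, ncol = 1L,
                                           dimnames = list(rownames(recording), NULL))
  colnames(vals) <- scales
  structure(list(
    values     = vals,
    mean       = colMeans(vals),
    scales     = scales,
    kind       = kind,
    m          = as.integer(m),
    tau        = as.integer(tau),
    subject_id = subject_id,
    group      = group
  ), class = "subject_profile")
}

#' Tidy long-format view of a subject profile
#'
#' @param x A `subject_profile`.
#' @param row.names,optional Ignored (S3 signature).
#' @param ... Ignored.
#' @return Data frame with columns `subject_id`, `group`, `channel`
#'   (channel label or `"MEAN"`), `scale`, `index_kind`, `value`.
#' @export
as.data.frame.subject_profile <- function(x, row.names = NULL, optional = FALSE, ...) {
  chans <- c(rownames(x$values), "MEAN")
  vals <- rbind(x$values, MEAN = x$mean)
  data.frame(
    subject_id = x$subject_id,
    group      = x$group,
    channel    = rep(chans, each = length(x$scales)),
    scale      = rep(x$scales, times = length(chans)),
    index_kind = x$kind,
    value      = as.vector(t(vals)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("Subject profile [%s]: %d channels, scales %d..%d (m = %d, tau = %d)\n",
              x$kind, nrow(x$values), min(x$scales), max(x$scales), x$m, x$tau))
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id, " group:", x$group, "\n")
  cat("  mean profile (first scales):\n")
  print(utils::head(round(x$mean, 4)))
  invisible(x)
}

#' Stack subject-level mean profiles into a subjects x scales matrix
#'
#' Convenience for feeding a list of [subject_profile()] results (or plain
#' numeric vectors) into [per_scale_ttest()].
#'
#' @param profiles List of `subject_profile` objects sharing one scale set.
#' @return Numeric matrix, one row per subject (named by `subject_id`),
#'   columns named by scale.
#' @export
profiles_matrix <- function(profiles) {
  stopifnot(length(profiles) > 0)
  scales <- profiles[[1]]$scales
  rows <- lapply(profiles, function(p) {
    if (!identical(p$scales, scales))
      stop("all subject profiles must share the same scale set")
    p$mean
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(profiles, function(p) p$subject_id, character(1))
  colnames(out) <- scales
  out
}
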