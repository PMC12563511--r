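# Per-scale two-group comparison of multiscale profiles: assumption
# checks, t tests (pooled or Welch), two-factor ANOVA, the log-base-0.05
# p transform used for reporting, and significance-interval summaries.

#' Normality and equal-variance assumption checks for two samples
#'
#' Kolmogorov-Smirnov tests of each group against a normal distribution
#' (with moments estimated from the sample) and an F test of variance
#' equality, each flagged at `alpha`.
#'
#' @param group_a,group_b Numeric vectors with at least 3 values each.
#' @param alpha Significance level for the flags (default 0.05).
#' @return List with `normal_p` (length-2 named vector), `normal_ok`
#'   (logical, per group), `variance_p`, `variance_ok`.
#' @export
assumption_checks <- function(group_a, group_b, alpha = 0.05) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) < 3L || length(group_b) < 3L)
    stop("each group needs at least 3 values for the assumption checks")
  ks_p <- function(v) {
    if (stats::sd(v) == 0) return(0)  # a point mass is maximally non-normal
    suppressWarnings(stats::ks.test(v, "pnorm", mean(v), stats::sd(v))$p.value)
  }
  normal_p <- c(a = ks_p(group_a), b = ks_p(group_b))
  variance_p <- if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) 1
                else stats::var.test(group_a, group_b)$p.value
  list(
    normal_p    = normal_p,
    normal_ok   = normal_p >= alpha,
    variance_p  = variance_p,
    variance_ok = variance_p >= alpha
  )
}

#' Per-scale two-sample t tests between two groups of profiles
#'
#' Runs a two-tailed independent-samples t test at every scale, comparing
#' the subject-level index values of the two groups. The pooled-variance
#' test is used where an F test accepts variance equality at `alpha`;
#' otherwise the Welch test is used. Group means and standard errors are
#' returned for plotting, and p values are also reported on the
#' log-base-0.05 scale (values above 1 mean p < 0.05).
#'
#' @param group_a,group_b Numeric matrices, subjects in rows and scales in
#'   columns (as from [profiles_matrix()]); column names must agree. Each
#'   group needs at least 2 subjects.
#' @param alpha Level used for the variance pre-check and downstream
#'   significance flags (default 0.05).
#' @param p_adjust Multiple-testing correction across scales, as in
#'   [stats::p.adjust()]. Default `"none"`, matching per-scale reporting;
#'   `"BH"` is available.
#' @return Data frame of class `cohort_result` with one row per scale:
#'   `scale`, `statistic` (t), `p_value`, `p_adjusted`, `neg_log05_p`,
#'   `test` (`"pooled"` or `"welch"`), `mean_a`, `mean_b`, `sem_a`,
#'   `sem_b`, `significant`.
#' @export
per_scale_ttest <- function(group_a, group_b, alpha = 0.05, p_adjust = "none") {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (nrow(group_a) < 2L || nrow(group_b) < 2L)
    stop("each group needs at least 2 subjects")
  if (ncol(group_a) != ncol(group_b) ||
      !identical(colnames(group_a), colnames(group_b)))
    stop("the two groups must cover the same scale set (identical columns)")
  scales <- if (is.null(colnames(group_a))) seq_len(ncol(group_a))
            else as.integer(colnames(group_a))
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  rows <- lapply(seq_len(ncol(group_a)), function(j) {
    a <- group_a[, j]; b <- group_b[, j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate: no within-group spread; identical means => no evidence
      tt <- list(statistic = c(t = if (mean(a) == mean(b)) 0 else Inf),
                 p.value = if (mean(a) == mean(b)) 1 else 0)
      eq <- TRUE
    } else {
      fp <- stats::var.test(a, b)$p.value
      eq <- fp >= alpha
      tt <- stats::t.test(a, b, var.equal = eq)
    }
    data.frame(scale = scales[j],
               statistic = unname(tt$statistic),
               p_value = tt$p.value,
               test = if (eq) "pooled" else "welch",
               mean_a = mean(a), mean_b = mean(b),
               sem_a = sem(a), sem_b = sem(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out$neg_log05_p <- log_p_transform(pmax(out$p_value, .Machine$double.xmin))
  out$significant <- out$p_adjusted < alpha
  class(out) <- c("cohort_result", "data.frame")
  out
}

#' Two-factor fixed-effects ANOVA at a single scale
#'
#' Standard two-way ANOVA with interaction, `value ~ group * level`, for
#' index values laid out by group (e.g. patients vs controls) and a second
#' factor (brain region or frequency band) at one fixed scale factor.
#'
#' @param data Data frame containing the response and the two factors.
#' @param value,group,level Column names (strings) of the response, the
#'   group factor and the second factor.
#' @return Data frame with one row per effect (`group`, the level factor,
#'   their interaction): `effect`, `df`, `sum_sq`, `statistic` (F),
#'   `p_value`. Effects whose sum of squares is exactly zero report
#'   `statistic = 0`.
#' @export
two_factor_anova <- function(data, value = "value", group = "group",
                             level = "level") {
  if (!all(c(value, group, level) %in% names(data)))
    stop("`data` must contain columns: ", paste(c(value, group, level), collapse = ", "))
  df <- data.frame(
    y = as.numeric(data[[value]]),
    g = factor(data[[group]]),
    l = factor(data[[level]])
  )
  if (nlevels(df$g) < 2L || nlevels(df$l) < 2L)
    stop("both factors need at least 2 levels")
  cell_n <- table(df$g, df$l)
  if (any(cell_n < 2L))
    stop("every (group, level) cell needs at least 2 observations; empty or singleton cells: ",
         sum(cell_n < 2L))
  labels0 <- c(group, level, paste0(group, ":", level))
  if (stats::var(df$y) == 0) {
    # identical values everywhere: all effects are exactly zero
    return(data.frame(
      effect = labels0,
      df = c(nlevels(df$g) - 1L, nlevels(df$l) - 1L,
             (nlevels(df$g) - 1L) * (nlevels(df$l) - 1L)),
      sum_sq = 0, statistic = 0, p_value = 1,
      stringsAsFactors = FALSE))
  }
  fit <- stats::aov(y ~ g * l, data = df)
  tab <- summary(fit)[[1]]
  eff <- trimws(rownames(tab))
  keep <- eff != "Residuals"
  fstat <- tab[keep, "F value"]
  ssq <- tab[keep, "Sum Sq"]
  fstat[ssq == 0] <- 0            # identical cells: zero effect, not NaN
  p <- tab[keep, "Pr(>F)"]
  p[ssq == 0] <- 1
  labels <- c(g = group, l = level, `g:l` = paste0(group, ":", level))
  data.frame(
    effect    = unname(labels[eff[keep]]),
    df        = tab[keep, "Df"],
    sum_sq    = ssq,
    statistic = fstat,
    p_value   = p,
    stringsAsFactors = FALSE
  )
}

#' Log-base-0.05 transform of p values
#'
#' `log(p) / log(0.05)`: the reporting transform in which `p = 0.05` maps
#' to 1, `p = 1` to 0, and smaller p values map to larger transformed
#' values (e.g. `p = 0.0025` to 2). Strictly decreasing in `p`.
#'
#' @param p Numeric vector of p values in `(0, 1]`.
#' @return Transformed values, same length as `p`.
#' @export
log_p_transform <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p values must lie in (0, 1]")
  log(p) / log(0.05)
}

#' Maximal runs of consecutive significant scales
#'
#' Scans per-scale test results for maximal runs of consecutive scale
#' factors with `p < alpha` and reports them as inclusive integer ranges
#' (the shape of a significance-interval summary table).
#'
#' @param results Data frame with columns `scale` (integers, sorted) and
#'   `p_value`, e.g. a [per_scale_ttest()] result.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with columns `start` and `end`, one row per run;
#'   zero rows when nothing is significant.
#' @examples
#' significance_intervals(data.frame(scale = 1:4, p_value = c(.04, .03, .2, .01)))
#' @export
significance_intervals <- function(results, alpha = 0.05) {
  if (!all(c("scale", "p_value") %in% names(results)))
    stop("`results` must have columns scale and p_value")
  o <- order(results$scale)
  sc <- as.integer(results$scale[o])
  sig <- results$p_value[o] < alpha
  runs <- data.frame(start = integer(0), end = integer(0))
  i <- 1L
  while (i <= length(sc)) {
    if (sig[i]) {
      j <- i
      while (j < length(sc) && sig[j + 1L] && sc[j + 1L] == sc[j] + 1L) j <- j + 1L
      runs <- rbind(runs, data.frame(start = sc[i], end = sc[j]))
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

#' Format significance intervals as a compact label
#'
#' @param intervals Result of [significance_intervals()].
#' @return A single string like `"[2,27] and [34,45]"`, or
#'   `"no significant difference"` when empty.
#' @export
format_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) return("no significant difference")
  paste(sprintf("[%d,%d]", intervals$start, intervals$end), collapse = " and ")
}
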