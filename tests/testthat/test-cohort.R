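test_that("assumption checks flag normality and variance homogeneity", {
  set.seed(41)
  a <- rnorm(200); b <- rnorm(200)
  chk <- assumption_checks(a, b)
  expect_true(all(chk$normal_ok))
  expect_true(chk$variance_ok)

  heavy <- rt(200, df = 1)          # Cauchy-tailed
  chk2 <- assumption_checks(heavy, b)
  expect_false(chk2$normal_ok[["a"]])

  same <- c(1.2, 3.4, 2.2, 4.1)
  chk3 <- assumption_checks(same, same)
  expect_equal(chk3$variance_p, 1)   # F = 1 for identical groups
  expect_true(chk3$variance_ok)
  expect_error(assumption_checks(c(1, 2), b), "at least 3")
})

test_that("per-scale t tests detect a constant shift at every scale", {
  set.seed(42)
  a <- matrix(rnorm(10 * 6, sd = 0.1), nrow = 10)
  b <- a + 1
  colnames(a) <- colnames(b) <- 1:6
  res <- per_scale_ttest(a, b)
  expect_true(all(res$p_value < 0.05))
  expect_true(all(res$significant))
  expect_equal(res$mean_b - res$mean_a, rep(1, 6), tolerance = 1e-12)
})

test_that("identical groups give t = 0 and p = 1", {
  a <- matrix(c(1, 2, 3, 4), nrow = 4, ncol = 3)
  colnames(a) <- 1:3
  res <- per_scale_ttest(a, a)
  expect_equal(res$statistic, rep(0, 3))
  expect_equal(res$p_value, rep(1, 3))
})

test_that("per-scale t tests validate their inputs", {
  a <- matrix(rnorm(8), nrow = 4, dimnames = list(NULL, 1:2))
  b <- matrix(rnorm(12), nrow = 4, dimnames = list(NULL, 1:3))
  expect_error(per_scale_ttest(a, b), "same scale set")
  expect_error(per_scale_ttest(a[1, , drop = FALSE], a), "at least 2 subjects")
})

test_that("type-I error under the null is near nominal and power grows with effect", {
  set.seed(43)
  reps <- 400
  rej <- replicate(reps, {
    res <- per_scale_ttest(matrix(rnorm(8 * 2), 8, 2, dimnames = list(NULL, 1:2)),
                           matrix(rnorm(8 * 2), 8, 2, dimnames = list(NULL, 1:2)))
    res$p_value < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)

  power_at <- function(delta) {
    mean(replicate(120, {
      a <- matrix(rnorm(8), 8, 1, dimnames = list(NULL, 1))
      b <- matrix(rnorm(8) + delta, 8, 1, dimnames = list(NULL, 1))
      per_scale_ttest(a, b)$p_value < 0.05
    }))
  }
  p <- vapply(c(0.5, 1, 2), power_at, numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_gt(p[3], 0.9)
})

test_that("Welch fallback engages when variances differ", {
  set.seed(44)
  a <- matrix(rnorm(30, sd = 1), 30, 1, dimnames = list(NULL, 1))
  b <- matrix(rnorm(30, sd = 6), 30, 1, dimnames = list(NULL, 1))
  expect_equal(per_scale_ttest(a, b)$test, "welch")
  b2 <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, 1))
  expect_equal(per_scale_ttest(a, b2)$test, "pooled")
})

test_that("two-factor ANOVA recovers injected effects", {
  set.seed(45)
  des <- expand.grid(group = c("HC", "SZ"), level = paste0("r", 1:4),
                     rep = 1:8)
  des$value <- rnorm(nrow(des), sd = 0.5) + ifelse(des$group == "SZ", 1, 0)
  tab <- two_factor_anova(des, value = "value", group = "group", level = "level")
  expect_equal(tab$effect, c("group", "level", "group:level"))
  expect_lt(tab$p_value[tab$effect == "group"], 0.05)
  expect_gt(tab$p_value[tab$effect == "group:level"], 0.05)
})

test_that("two-factor ANOVA handles identical cells and rejects bad designs", {
  des <- expand.grid(group = c("A", "B"), level = c("x", "y"), rep = 1:3)
  des$value <- 2
  tab <- two_factor_anova(des)
  expect_equal(tab$statistic, rep(0, 3))
  expect_equal(tab$p_value, rep(1, 3))
  expect_error(two_factor_anova(des[des$group == "A", ]), "at least 2 levels")
  expect_error(two_factor_anova(des[-c(1, 5, 9), ]), "cell")
  expect_error(two_factor_anova(data.frame(x = 1)), "must contain")
})

test_that("ANOVA null calibration: rejection rate near nominal for all effects", {
  set.seed(46)
  rej <- replicate(200, {
    des <- expand.grid(group = c("A", "B"), level = c("x", "y", "z"), rep = 1:4)
    des$value <- rnorm(nrow(des))
    two_factor_anova(des)$p_value < 0.05
  })
  rate <- rowMeans(rej)
  expect_true(all(rate > 0.005 & rate < 0.12))
})

test_that("the log-base-0.05 transform maps its anchors and inverts cleanly", {
  expect_equal(log_p_transform(0.05), 1)
  expect_equal(log_p_transform(1), 0)
  expect_equal(log_p_transform(0.0025), 2)
  p <- c(0.9, 0.2, 0.05, 1e-4)
  expect_true(all(diff(log_p_transform(p)) > 0))  # decreasing in p
  expect_equal(0.05^log_p_transform(p), p, tolerance = 1e-12)
  expect_error(log_p_transform(0), "\\(0, 1\\]")
  expect_error(log_p_transform(1.2), "\\(0, 1\\]")
})

test_that("significance intervals are maximal runs of consecutive scales", {
  res <- data.frame(scale = 1:4, p_value = c(0.04, 0.03, 0.2, 0.01))
  expect_equal(significance_intervals(res),
               data.frame(start = c(1L, 4L), end = c(2L, 4L)))
  none <- data.frame(scale = 1:5, p_value = rep(0.5, 5))
  expect_equal(nrow(significance_intervals(none)), 0L)
  all_sig <- data.frame(scale = 2:100, p_value = rep(0.01, 99))
  expect_equal(significance_intervals(all_sig),
               data.frame(start = 2L, end = 100L))
  # non-consecutive scales never merge
  gap <- data.frame(scale = c(1, 2, 5, 6), p_value = rep(0.01, 4))
  expect_equal(significance_intervals(gap),
               data.frame(start = c(1L, 5L), end = c(2L, 6L)))
  expect_equal(format_intervals(significance_intervals(res)),
               "[1,2] and [4,4]")
  expect_equal(format_intervals(significance_intervals(none)),
               "no significant difference")
})
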