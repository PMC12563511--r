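test_that("amplitude permutation follows the stable-sort minimum-rank rule", {
  expect_identical(amplitude_permutation(c(4, 7, 2)), c(2L, 3L, 1L))
  expect_identical(amplitude_permutation(c(5, 5, 3)), c(2L, 2L, 1L))
  expect_identical(amplitude_permutation(c(3, 3, 3)), c(1L, 1L, 1L))
  expect_identical(amplitude_permutation(c(-1.5, 0, -1.5, 2)),
                   c(1L, 3L, 1L, 4L))
  # agrees with the naive stable-sort oracle on random vectors incl. ties
  set.seed(101)
  for (i in 1:50) {
    m <- sample(2:6, 1)
    v <- sample(1:3, m, replace = TRUE) + stats::rnorm(m, sd = 0.01 * (i %% 2))
    expect_identical(amplitude_permutation(v), as.integer(oracle_amp_perm(v)))
  }
})

test_that("amplitude permutation rejects invalid input", {
  expect_error(amplitude_permutation(5), "at least 2")
  expect_error(amplitude_permutation(c(1, NA, 2)), "non-finite")
  expect_error(amplitude_permutation(c(1, Inf, 2)), "non-finite")
  expect_error(amplitude_permutation(c(1, 2), tie_tol = -1), "nonnegative")
})

test_that("tie tolerance merges nearby values pairwise", {
  expect_identical(amplitude_permutation(c(1, 1.05, 3), tie_tol = 0.1),
                   c(1L, 1L, 3L))
  expect_identical(amplitude_permutation(c(1, 1.05, 3), tie_tol = 0),
                   c(1L, 2L, 3L))
})

test_that("backward permutation is the tuple reversal", {
  expect_identical(backward_permutation(c(2L, 3L, 1L)), c(1L, 3L, 2L))
  expect_identical(backward_permutation(c(1L, 2L, 3L)), c(3L, 2L, 1L))
  expect_identical(backward_permutation(c(1L, 1L, 1L)), c(1L, 1L, 1L))
  expect_error(backward_permutation(c(0L, 1L)), "not a valid")
})

test_that("pattern distribution matches hand-enumerated examples", {
  d <- pattern_distribution(c(1, 2, 3, 4, 5), m = 3, tau = 1)
  expect_equal(d$prob, c("1,2,3" = 1))
  expect_equal(d$U, 1L)
  expect_equal(d$V, 2L)
  expect_equal(d$n_vectors, 3L)

  d2 <- pattern_distribution(c(1, 2, 1, 2, 1), m = 2, tau = 1)
  expect_equal(d2$prob[order(names(d2$prob))], c("1,2" = 0.5, "2,1" = 0.5))
  expect_equal(d2$U, 2L)
  expect_equal(d2$V, 2L)

  d3 <- pattern_distribution(rep(4.2, 30), m = 3, tau = 2)
  expect_equal(d3$prob, c("1,1,1" = 1))
  expect_equal(d3$U, 1L)
  expect_equal(d3$V, 1L)  # the all-ties pattern is self-reverse
})

test_that("pattern distribution validates its inputs and reports minimum length", {
  expect_error(pattern_distribution(c(1, 2, 3), m = 3, tau = 2), "minimum 5")
  expect_error(pattern_distribution(1:10, m = 1), "2..8")
  expect_error(pattern_distribution(1:10, m = 9), "2..8")
  expect_error(pattern_distribution(1:10, m = 3, tau = 0), "positive")
  expect_error(pattern_distribution(c(1, NaN, 3, 4, 5)), "non-finite")
})

test_that("probabilities are consistent counts and U <= V <= 2U", {
  set.seed(11)
  for (i in 1:20) {
    m <- sample(2:4, 1); tau <- sample(1:3, 1)
    x <- stats::rnorm(100)
    d <- pattern_distribution(x, m = m, tau = tau)
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
    expect_equal(unname(d$prob), unname(d$counts / d$n_vectors))
    expect_true(d$U <= d$V && d$V <= 2 * d$U)
    expect_equal(d$n_vectors, length(x) - (m - 1) * tau)
  }
})

test_that("permutation entropy handles closed-form cases, bases, normalization", {
  # uniform over the 6 tie-free patterns at m = 3, via construction:
  # repeating all 6 orderings yields an exactly uniform pattern distribution
  set.seed(3)
  x <- stats::rnorm(6e4)
  d <- pattern_distribution(x, m = 3, tau = 1)
  expect_equal(permutation_entropy(d), log(6), tolerance = 1e-3)
  ramp <- pattern_distribution(1:20, m = 3, tau = 1)
  expect_equal(permutation_entropy(ramp), 0)
  d2 <- pattern_distribution(c(1, 2, 1, 2, 1), m = 2, tau = 1)
  expect_equal(permutation_entropy(d2), log(2))
  expect_equal(permutation_entropy(d2, base = 2), 1)
  expect_equal(permutation_entropy(d2, normalized = TRUE), 1)
})

test_that("PTIRR closed forms: ramp, symmetric, and 3:1 asymmetric cases", {
  ramp <- pattern_distribution(1:20, m = 3, tau = 1)
  expect_equal(permutation_time_irreversibility(ramp), 1)
  d2 <- pattern_distribution(c(1, 2, 1, 2, 1), m = 2, tau = 1)  # p = p_rev
  expect_equal(permutation_time_irreversibility(d2), 0)
  const <- pattern_distribution(rep(1, 20), m = 3, tau = 1)
  expect_equal(permutation_time_irreversibility(const), 0)
  # 3 increasing + 1 decreasing length-2 patterns: |0.75 - 0.25| = 0.5
  d3 <- pattern_distribution(c(1, 2, 3, 4, 3), m = 2, tau = 1)
  expect_equal(unname(d3$prob["1,2"]), 0.75)
  expect_equal(permutation_time_irreversibility(d3), 0.5)
})

test_that("pattern distribution serializes to JSON with counts by rank tuple", {
  d <- pattern_distribution(c(1, 2, 3, 2, 1), m = 2, tau = 1)
  parsed <- jsonlite::fromJSON(pattern_distribution_json(d))
  expect_equal(parsed$n_vectors, 4)
  expect_equal(parsed$counts$`1,2`, 2)
  expect_equal(parsed$counts$`2,1`, 2)
  expect_equal(parsed$U, 2)
})
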