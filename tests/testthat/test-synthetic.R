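test_that("Gaussian AR generator matches its theory and is reproducible", {
  x <- gen_gaussian_ar(1e5, seed = 1)
  expect_lt(abs(mean(x)), 4 / sqrt(1e5))
  y <- gen_gaussian_ar(1e5, 0.9, seed = 2)
  r1 <- cor(y[-1], y[-length(y)])
  expect_lt(abs(r1 - 0.9), 0.05)
  expect_identical(gen_gaussian_ar(500, 0.5, seed = 3),
                   gen_gaussian_ar(500, 0.5, seed = 3))
  expect_error(gen_gaussian_ar(100, 1.1), "nonstationary")
  expect_error(gen_gaussian_ar(0), "positive")
})

test_that("logistic map iterates exactly and stays in its invariant interval", {
  expect_equal(gen_logistic_map(2, x0 = 0.2, transient = 0), c(0.64, 0.9216))
  x <- gen_logistic_map(5000, x0 = 0.3)
  expect_true(all(x >= 0 & x <= 1))
  expect_error(gen_logistic_map(10, x0 = 1.5), "inside \\(0, 1\\)")
  expect_error(gen_logistic_map(10, r = 5), "\\(0, 4\\]")
})

test_that("phase-randomized surrogates keep the power spectrum, kill asymmetry", {
  x <- gen_logistic_map(4096, x0 = 0.27)
  s <- phase_randomized_surrogate(x, seed = 7)
  expect_equal(Mod(fft(s)), Mod(fft(x)), tolerance = 1e-8)
  expect_identical(phase_randomized_surrogate(x, seed = 7), s)
  ptirr <- function(v) permutation_time_irreversibility(
    pattern_distribution(v, m = 3, tau = 1))
  expect_gt(ptirr(x), 0.4)
  expect_lt(ptirr(s), 0.05)
  expect_error(phase_randomized_surrogate(rnorm(10)), "at least 64")
})

test_that("pink noise has a 1/f-sloped spectrum and unit variance", {
  z <- pink_noise(2^14, seed = 9)
  expect_equal(sd(z), 1, tolerance = 1e-8)
  spec <- Mod(fft(z))^2
  k <- 2:2000
  slope <- coef(lm(log(spec[k]) ~ log(k)))[2]
  expect_lt(abs(slope + 1), 0.25)
})

test_that("burst train is strongly irreversible across the scale range", {
  z <- gen_burst_train(5e4, seed = 10)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  pr <- ms_profile(z, scales = c(1, 4, 10, 20), m = 3, tau = 2, kind = "PTIRR")
  expect_true(all(pr$value > 0.1))
  expect_identical(gen_burst_train(1000, seed = 4), gen_burst_train(1000, seed = 4))
  expect_error(gen_burst_train(100, decay = -1), "positive")
})

test_that("reversible generators sit inside the irreversibility null band", {
  ptirr2 <- function(v) permutation_time_irreversibility(
    pattern_distribution(v, m = 3, tau = 2))
  expect_lt(ptirr2(gen_gaussian_ar(1e5, seed = 21)), 0.02)
  expect_lt(ptirr2(gen_gaussian_ar(1e5, c(0.6, 0.2), seed = 22)), 0.02)
  expect_lt(ptirr2(phase_randomized_surrogate(gen_burst_train(1e5, seed = 23),
                                              seed = 24)), 0.02)
})

test_that("cohort recordings have the declared geometry and CTF-style labels", {
  coh <- make_small_cohort(seed = 31)
  expect_equal(length(coh$subjects), 10L)
  expect_equal(coh$manifest$group, rep(c("HC", "SZ"), each = 5))
  expect_equal(coh$manifest$mix, rep(c(0.3, 0.1), each = 5))
  rec <- coh$subjects[[1]]$data
  expect_equal(dim(rec), c(6L, 3000L))
  rm <- map_regions(rownames(rec))
  expect_true(all(rm$assigned))
  expect_equal(sd(rec[1, ]), 1, tolerance = 0.1)  # unit-variance mixing
  expect_error(gen_cohort(n_per_group = c(2, 2), irreversibility_mix = c(2, 0)),
               "\\[0, 1\\]")
  expect_error(gen_cohort(n_per_group = 3), "two positive counts")
})

test_that("cohorts are bit-reproducible for a fixed seed", {
  a <- make_small_cohort(seed = 5, n_per_group = c(A = 2, B = 2),
                         n_channels = 2, n_samples = 500)
  b <- make_small_cohort(seed = 5, n_per_group = c(A = 2, B = 2),
                         n_channels = 2, n_samples = 500)
  expect_identical(a$subjects[[4]]$data, b$subjects[[4]]$data)
})

test_that("the group PTIRR contrast grows with the mix gap", {
  mean_ptirr <- function(mix) {
    coh <- gen_cohort(n_per_group = c(A = 4, B = 4), n_channels = 6,
                      n_samples = 6000, sample_rate_hz = 300,
                      irreversibility_mix = c(A = mix, B = mix), seed = 11)
    mean(vapply(coh$subjects[1:4], function(s)
      mean(subject_profile(s$data, scales = c(2, 4, 8), kind = "PTIRR")$mean),
      numeric(1)))
  }
  vals <- vapply(c(0.05, 0.2, 0.5), mean_ptirr, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("study-scale geometry generates and processes end to end", {
  coh <- gen_cohort(n_per_group = c(HC = 1, SZ = 1), n_channels = 275,
                    n_samples = 144000, sample_rate_hz = 1200, seed = 13)
  rec <- coh$subjects[[1]]$data
  expect_equal(dim(rec), c(275L, 144000L))
  sp <- subject_profile(rec[1:3, ], scales = c(1, 10, 100), kind = "PTIRR")
  expect_true(all(is.finite(sp$mean)) && all(sp$mean >= 0 & sp$mean <= 1))
})
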