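test_that("identical groups give zero difference and p = 1", {
  pt <- permutation_test(c(1, 2, 3, 4), c(1, 2, 3, 4), n_perm = 999, seed = 1)
  expect_identical(pt$observed_diff, 0)
  expect_identical(pt$p_value, 1)
})

test_that("permutation p-values are bit-reproducible given a seed", {
  a <- c(1.1, 2.3, 0.7, 1.9); b <- c(2.0, 3.1, 2.8, 2.2)
  p1 <- permutation_test(a, b, n_perm = 2000, seed = 42)
  p2 <- permutation_test(a, b, n_perm = 2000, seed = 42)
  expect_identical(p1$p_value, p2$p_value)
  expect_gt(p1$p_value, 0)  # add-one rule: never exactly 0
})

test_that("type-I error is calibrated and p-values are super-uniform under the null", {
  set.seed(101)
  n_rep <- 1000
  pvals <- vapply(seq_len(n_rep), function(i) {
    a <- rnorm(6); b <- rnorm(6)
    permutation_test(a, b, n_perm = 999, seed = i)$p_value
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
  # super-uniformity at several alpha levels (Monte Carlo slack 3 sd)
  for (alpha in c(0.01, 0.1, 0.25)) {
    slack <- 3 * sqrt(alpha * (1 - alpha) / n_rep)
    expect_lte(mean(pvals < alpha), alpha + slack)
  }
})

test_that("the test has power against a 3-SD mean shift at n = 8", {
  set.seed(202)
  rej <- vapply(seq_len(200), function(i) {
    a <- rnorm(8); b <- rnorm(8, mean = 3)
    permutation_test(a, b, n_perm = 999, seed = i)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.95)
})

test_that("rank test pass-through matches expectations on edge cases", {
  expect_gte(rank_test_passthrough(c(1, 2, 3), c(1, 2, 3)), 0.99)
  # fully separated samples at n = 3 vs 3: exact two-sided p = 0.1
  p_sep <- rank_test_passthrough(c(1, 2, 3), c(10, 11, 12))
  expect_lt(p_sep, 0.11)
  expect_identical(rank_test_passthrough(c(1, 5, 3), c(2, 9, 4)),
                   rank_test_passthrough(c(2, 9, 4), c(1, 5, 3)))
  expect_error(rank_test_passthrough(numeric(), 1:3), "empty")
})
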