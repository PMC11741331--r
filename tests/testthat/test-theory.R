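test_that("detectability tail probabilities evaluate and order correctly", {
  expect_equal(tail_prob_right(0, 50), 1)
  expect_equal(tail_prob_right(0.01, 100), exp(-1))
  expect_equal(tail_prob_width(0, 50), 1)
  expect_equal(tail_prob_width(0.02, 100), 3 * exp(-2))
  w <- seq(0, 0.1, by = 0.01); g <- c(10, 100, 400)
  for (gg in g) {
    expect_true(all(diff(tail_prob_right(w, gg)) <= 0))
    expect_true(all(tail_prob_width(w, gg) >= tail_prob_right(w, gg)))
  }
  expect_true(all(diff(tail_prob_right(0.01, c(10, 100, 1000))) < 0))
  expect_error(tail_prob_right(-0.1, 10), "non-negative")
})

test_that("expected coalescent times reproduce the harmonic-difference form", {
  expect_equal(expected_coal_time(2, 2), 1)
  expect_equal(expected_coal_time(10, 2), 2 * (1 - 1 / 10))
  expect_equal(round(expected_coal_time_gen(Inf, 40, 1e4), 2), 512.82)
  expect_equal(round(expected_coal_time_gen(Inf, 400, 1e5), 2), 501.25)
  # direct sum oracle: sum over l = k..n of 1/choose(l, 2)
  direct <- sum(1 / choose(40:2000, 2))
  expect_equal(expected_coal_time(2000, 40), direct, tolerance = 1e-12)
  expect_error(expected_coal_time(10, 1), "at least 2")
})

test_that("shared endpoint probability matches the exponential race", {
  expect_equal(shared_endpoint_prob(1, 1), 1 / 3)
  expect_equal(shared_endpoint_prob(1, 2), 0.5)
  expect_lt(shared_endpoint_prob(1, 1e-9), 1e-8)
  expect_gt(shared_endpoint_prob(1, 1e9), 1 - 1e-8)
  set.seed(11)
  R <- 1e5; u <- 1; v <- 2
  ra <- rexp(R, u); rb <- rexp(R, u); rc <- rexp(R, v)
  freq <- mean(rc < pmin(ra, rb))
  p <- shared_endpoint_prob(u, v)
  expect_lt(abs(freq - p), 3 * sqrt(p * (1 - p) / R))
})

test_that("the rank-substituted shared-endpoint probability and its limit", {
  expect_equal(prop1_prob(1000, 100, 10), 90000 / 108000)
  # algebraic identity with the u, v substitution
  n <- 5000; k <- 120; j <- 17
  u <- 2 * (1 / k - 1 / n); v <- 2 * (1 / j - 1 / k)
  expect_equal(prop1_prob(n, k, j), shared_endpoint_prob(u, v),
               tolerance = 1e-12)
  # tends to 1 as j/k -> 0
  expect_gt(prop1_prob(1e6, 1e4, 10), 0.99)
  expect_lt(prop1_prob(100, 50, 49), 0.03)
  expect_error(prop1_prob(10, 5, 5), "j < k")
})

test_that("expected comparisons at a bifurcation match enumeration and MC", {
  # exhaustive enumeration at n = 4: all 2^4 equiprobable left/right splits
  splits <- as.matrix(expand.grid(rep(list(0:1), 4)))
  b1 <- rowSums(splits)
  expect_equal(mean(b1 * (4 - b1)), 3)
  expect_equal(expected_comparisons(4, 1), 3)
  expect_equal(expected_comparisons(2, 1), 0.5)
  set.seed(21)
  R <- 1e5; n <- 256
  b1 <- rbinom(R, n, 0.5)
  b2 <- rbinom(R, b1, 0.5)
  x <- b2 * (b1 - b2)
  expect_lt(abs(mean(x) - expected_comparisons(n, 2)),
            3 * sd(x) / sqrt(R))
})

test_that("variance of the comparison count scales like n^3", {
  set.seed(31)
  R <- 1e5
  v <- vapply(c(256, 1024), function(n) {
    b1 <- rbinom(R, n, 0.5)
    b2 <- rbinom(R, b1, 0.5)
    var(b2 * (b1 - b2))
  }, numeric(1))
  ratio <- v[2] / v[1]
  expect_gt(ratio, 4^3 * 0.5)
  expect_lt(ratio, 4^3 * 2.0)
})

test_that("expected parent count matches the occupancy simulation", {
  expect_equal(expected_parents(2e4, 2e5), 19000.05)
  expect_true(expected_parents(50, 1e6) < 50)
  set.seed(41)
  k <- 20; N <- 2000; R <- 2000
  distinct <- vapply(seq_len(R), function(i) {
    length(unique(sample.int(N, k, replace = TRUE)))
  }, numeric(1))
  # second-order approximation error is O(choose(k,3)/N^2)
  slack <- choose(k, 3) / N^2 + 3 * sd(distinct) / sqrt(R)
  expect_lt(abs(mean(distinct) - expected_parents(k, N)), slack)
})

test_that("binomial validity ratio is the cubed sampling fraction", {
  expect_equal(binomial_validity_ratio(2e4, 2e5), 1e-3)
  expect_equal(binomial_validity_ratio(100, 100), 1)
  expect_true(all(diff(binomial_validity_ratio(c(10, 20, 40), 1000)) > 0))
  expect_true(all(diff(binomial_validity_ratio(10, c(100, 200, 400))) < 0))
})
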