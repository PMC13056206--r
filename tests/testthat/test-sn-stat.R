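test_that("segment means and partial-sum processes match hand values", {
  r <- c(1, 2, 3, 4)
  expect_equal(segment_mean(r, 1, 2), 1.5)
  expect_equal(segment_mean(r, 3, 4), 3.5)
  expect_equal(segment_mean(r, 2, 2), 2)  # singleton segment
  expect_error(segment_mean(r, 3, 2), "<=")

  expect_equal(partial_sum_process(r, 1, 4), c(-1.5, -2.0, -1.5, 0.0))
  expect_equal(partial_sum_process(c(7, 7, 7), 1, 3), c(0, 0, 0))
})

test_that("the last centered partial sum is always zero", {
  set.seed(51)
  for (i in 1:20) {
    e <- rnorm(sample(5:50, 1))
    j <- sample(seq_along(e), 1)
    k <- j + sample.int(length(e) - j + 1, 1) - 1L
    s <- partial_sum_process(e, j, k)
    expect_lt(abs(s[length(s)]), 1e-10)
  }
})

test_that("Gn matches its complete hand evaluation and conventions", {
  # numerator 4*|1.5-3.5| = 8; sum St^2 = 0.5; denominator sqrt(0.5/4)
  expect_equal(sn_gn(c(1, 2, 3, 4), 2), 8 / sqrt(0.5 / 4), tolerance = 1e-12)
  expect_equal(sn_gn(c(1, 2, 3, 4), 2), 22.62742, tolerance = 1e-6)
  # zero numerator
  expect_equal(sn_gn(c(1, -1, 1, -1), 2), 0)
  # degenerate denominator with positive numerator
  expect_warning(g <- sn_gn(c(1, 1, 2, 2), 2), "degenerate")
  expect_identical(g, Inf)
  expect_error(sn_gn(c(1, 2, 3), 3), "k < n")
})

test_that("optimized profile equals the literal quadratic-time oracle", {
  set.seed(52)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    e <- as.numeric(sample(-5:5, n, replace = TRUE))
    st <- sn_statistic(e)
    lit <- vapply(st$profile$k, function(k) oracle_gn(e, k), numeric(1))
    if (any(is.infinite(lit))) {
      expect_identical(is.infinite(st$profile$gn), is.infinite(lit))
      fin <- is.finite(lit)
      expect_equal(st$profile$gn[fin], lit[fin], tolerance = 1e-9)
    } else {
      expect_equal(st$profile$gn, lit, tolerance = 1e-9)
    }
  }
})

test_that("Gn is invariant to residual scale and location", {
  set.seed(53)
  for (i in 1:10) {
    e <- rnorm(80)
    base <- sn_statistic(e)
    cc <- runif(1, 0.1, 10)
    sc <- sn_statistic(cc * e)
    sh <- sn_statistic(e + runif(1, -50, 50))
    expect_equal(sc$profile$gn, base$profile$gn, tolerance = 1e-9)
    expect_equal(sh$profile$gn, base$profile$gn, tolerance = 1e-8)
    expect_identical(sc$k_hat, base$k_hat)
    expect_true(all(base$profile$gn >= 0))
  }
})

test_that("Tn is the profile supremum and k-hat the first argmax", {
  set.seed(54)
  e <- rnorm(200)
  st <- sn_statistic(e)
  expect_equal(st$statistic, max(st$profile$gn))
  expect_equal(st$k_hat, st$profile$k[which.max(st$profile$gn)])
  expect_equal(range(st$profile$k), c(ceiling(200 * 0.15), floor(200 * 0.85)))
  # window with a single candidate
  st2 <- sn_statistic(e, trim = c(0.498, 0.502))
  expect_equal(st2$profile$k, 100L)
  expect_equal(st2$statistic, sn_gn(e, 100))
})

test_that("too-short series fail with the minimum length stated", {
  expect_error(sn_statistic(rnorm(5)), "need n >=")
  expect_error(sn_statistic(rnorm(5), trim = c(0.3, 0.2)), "tau1 < tau2")
})
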