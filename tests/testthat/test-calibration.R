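test_that("critical values follow the ceiling order-statistic convention", {
  ns <- null_samples(1:100, "finite_sample", 100, c(0.15, 0.85), 1, "sn")
  expect_equal(critical_value(ns, 0.05), 95)
  expect_equal(critical_value(ns, 0.10), 90)
  # monotone in alpha
  expect_gte(critical_value(ns, 0.05), critical_value(ns, 0.10))
  # point mass
  ns_c <- null_samples(rep(3.5, 200), "finite_sample", 100, c(0.15, 0.85), 1, "sn")
  expect_equal(critical_value(ns_c, 0.05), 3.5)
  expect_equal(critical_value(ns_c, 0.5), 3.5)
  expect_error(critical_value(ns, 0.01), "too few")
  expect_error(critical_value(ns, 1.5), "in \\(0, 1\\)")
})

test_that("Monte Carlo p-values use the add-one rule", {
  ns <- null_samples(seq_len(999), "finite_sample", 100, c(0.15, 0.85), 1, "sn")
  expect_equal(p_value(1000, ns), 1 / 1000)        # above every sample
  expect_equal(p_value(1, ns), 1)                  # at the minimum
  expect_equal(p_value(500, ns), 501 / 1000)       # near the median
})

test_that("null simulation is seeded and produces finite positive draws", {
  a <- simulate_null_Tn(100, 200, seed = 61)
  b <- simulate_null_Tn(100, 200, seed = 61)
  expect_identical(a$samples, b$samples)
  expect_true(all(is.finite(a$samples)) && all(a$samples > 0))
  expect_equal(a$reps, 200)
  l1 <- simulate_limit_functional(grid = 300, reps = 150, seed = 62)
  l2 <- simulate_limit_functional(grid = 300, reps = 150, seed = 62)
  expect_identical(l1$samples, l2$samples)
  expect_error(simulate_null_Tn(100, 50, seed = 1), "at least 100")
  expect_error(simulate_limit_functional(grid = 100, reps = 200), "at least 200")
})

test_that("narrowing the trimming window shrinks the supremum quantile", {
  wide <- simulate_limit_functional(grid = 400, reps = 2000, seed = 63)
  narrow <- simulate_limit_functional(grid = 400, reps = 2000,
                                      trim = c(0.4, 0.6), seed = 63)
  expect_lt(critical_value(narrow, 0.05), critical_value(wide, 0.05))
})

test_that("refitting the null model barely moves the upper quantile", {
  direct <- simulate_null_Tn(300, 4000, seed = 64)
  refit <- simulate_null_Tn(300, 1000, seed = 64, order = c(1, 0),
                            params = arma_params(phi = 0.3), refit = TRUE)
  q_direct <- critical_value(direct, 0.05)
  q_refit <- critical_value(refit, 0.05)
  expect_lt(abs(q_refit / q_direct - 1), 0.10)
})

test_that("critical-value tables round-trip losslessly through CSV", {
  ns <- simulate_null_Tn(100, 600, seed = 65)
  tab <- cv_table(ns)
  f1 <- file.path(tempdir(), "cv1.csv"); f2 <- file.path(tempdir(), "cv2.csv")
  write_critical_values(tab, f1)
  back <- read_critical_values(f1)
  write_critical_values(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(back$critical_value, tab$critical_value, tolerance = 1e-12)
  unlink(c(f1, f2))
  # the shipped table loads and covers the default trimming at 5%
  shipped <- shipped_critical_values()
  expect_true(any(shipped$alpha == 0.05 & shipped$tau1 == 0.15))
  expect_true(all(shipped$critical_value > 0))
})
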