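test_that("recursive residuals follow the zero-initial-condition recursion", {
  # hand-checked values
  expect_equal(as.numeric(arma_residuals(c(1, 0, 0), arma_params(phi = 0.5))),
               c(1, -0.5, 0))
  expect_equal(as.numeric(arma_residuals(c(1, 1), arma_params(phi = 0, theta = 0.5))),
               c(1, 0.5))
  # order (0,0): empty sums, residuals are the series
  y <- rnorm(20)
  expect_equal(as.numeric(arma_residuals(y, arma_params())), y)
  # random ARMA parameter sets against the literal loop oracle
  set.seed(11)
  for (i in 1:25) {
    p <- sample(0:3, 1); q <- sample(0:3, 1)
    phi <- runif(p, -0.5, 0.5); theta <- runif(q, -0.5, 0.5)
    y <- rnorm(sample(10:60, 1))
    expect_equal(as.numeric(arma_residuals(y, arma_params(phi, theta))),
                 oracle_residuals(y, phi, theta), tolerance = 1e-12)
  }
})

test_that("re-substituting residuals into the model reproduces the series", {
  set.seed(12)
  for (i in 1:10) {
    p <- sample(0:2, 1); q <- sample(0:2, 1)
    phi <- runif(p, -0.5, 0.5); theta <- runif(q, -0.5, 0.5)
    y <- rnorm(40)
    e <- as.numeric(arma_residuals(y, arma_params(phi, theta)))
    n <- length(y)
    y_back <- numeric(n)
    for (t in seq_len(n)) {
      acc <- e[t]
      for (ii in seq_along(phi)) if (t > ii) acc <- acc + phi[ii] * y_back[t - ii]
      for (jj in seq_along(theta)) if (t > jj) acc <- acc + theta[jj] * e[t - jj]
      y_back[t] <- acc
    }
    expect_equal(y_back, y, tolerance = 1e-10)
  }
})

test_that("with q = 0 a residual depends only on current and lagged observations", {
  set.seed(13)
  y <- rnorm(30)
  e <- arma_residuals(y, arma_params(phi = c(0.4, -0.2)))
  y2 <- y
  y2[21] <- y2[21] + 100  # perturb the future
  e2 <- arma_residuals(y2, arma_params(phi = c(0.4, -0.2)))
  expect_identical(e[1:20], e2[1:20])
})

test_that("dimension mismatches and invalid inputs are contract errors", {
  expect_error(arma_residuals(rnorm(10), arma_params(phi = 0.5), order = c(2, 0)),
               "does not match")
  expect_error(arma_residuals(c(1, NA, 3), arma_params(phi = 0.5)), "non-finite")
  expect_error(fit_arma_qmle(c(rnorm(5), Inf), c(1, 0)), "non-finite")
  expect_error(fit_arma_qmle(rnorm(15), c(1, 1)), "too short")
  expect_error(arma_params(phi = 0.5, sigma2 = -1), "positive")
})

test_that("QMLE recovers known generating parameters", {
  y <- simulate_arma(arma_params(phi = 0.5), n = 5000, seed = 21)
  fit <- fit_arma_qmle(y, c(1, 0))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$phi - 0.5), 0.05)
  expect_equal(fit$n_used, 5000)

  # white noise fitted as AR(1): phi-hat near zero
  set.seed(22)
  fit0 <- fit_arma_qmle(rnorm(5000), c(1, 0))
  expect_lt(abs(fit0$params$phi), 0.05)

  # degenerate order: sigma2 is the mean squared deviation about the mean
  set.seed(23)
  y <- rnorm(200, mean = 3)
  fitn <- fit_arma_qmle(y, c(0, 0))
  expect_length(fitn$params$phi, 0)
  expect_length(fitn$params$theta, 0)
  expect_equal(fitn$params$sigma2, mean((y - mean(y))^2))
})

test_that("QMLE is unbiased and stable across replicates", {
  phis <- vapply(1:200, function(i) {
    y <- simulate_arma(arma_params(phi = 0.5), n = 1000, seed = 3000 + i)
    fit_arma_qmle(y, c(1, 0))$params$phi
  }, numeric(1))
  expect_lt(abs(mean(phis) - 0.5), 0.02)
  expect_lt(sd(phis), 0.05)
})

test_that("stationarity and invertibility are flagged, not enforced", {
  p_bad <- arma_params(phi = 1.2)
  expect_false(is_stationary(p_bad))
  expect_true(is_invertible(p_bad))
  expect_warning(simulate_arma(p_bad, n = 50, seed = 1), "not stationary")
  expect_true(is_stationary(arma_params(phi = c(0.5, 0.3))))
  expect_false(is_invertible(arma_params(theta = -1.5)))
})
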