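test_that("simulation is reproducible and matches first and second moments", {
  # determinism
  expect_identical(simulate_arma(arma_params(phi = 0.5), 100, seed = 41),
                   simulate_arma(arma_params(phi = 0.5), 100, seed = 41))
  # i.i.d. case: unit variance
  y0 <- simulate_arma(arma_params(), n = 1e5, seed = 42)
  expect_lt(abs(var(y0) - 1), 0.02)
  # AR(1): lag-1 autocorrelation equals phi
  y1 <- simulate_arma(arma_params(phi = 0.5), n = 1e5, seed = 43)
  r1 <- cor(y1[-1], y1[-length(y1)])
  expect_lt(abs(r1 - 0.5), 0.02)
  expect_error(simulate_arma(arma_params(), n = 0), ">= 1")
})

test_that("a no-change specification reduces exactly to plain simulation", {
  par <- arma_params(phi = 0.3, theta = 0.3)
  dgp <- changepoint_dgp(c(1, 1), par)
  s <- simulate_changepoint(dgp, 300, seed = 44)
  expect_identical(s$values, simulate_arma(par, 300, seed = 44))
  expect_null(s$true_break_index)
  # a zero-size break (identical regimes) also leaves the path unchanged:
  # the recursion state carries across the break with no reset
  dgp0 <- changepoint_dgp(c(1, 1), par, par, break_fraction = 0.5)
  s0 <- simulate_changepoint(dgp0, 300, seed = 44)
  expect_identical(s0$values, simulate_arma(par, 300, seed = 44))
  expect_identical(s0$true_break_index, 150L)
})

test_that("post-break moments reflect the specified change", {
  par <- arma_params(phi = 0.3)
  # mean shift of 2 at mid-sample
  dgp_mu <- changepoint_dgp(c(1, 0), par, par, break_fraction = 0.5, mean_shift = 2)
  s <- simulate_changepoint(dgp_mu, 1e4, seed = 45)
  k <- s$true_break_index
  expect_equal(k, 5000L)
  expect_lt(abs((mean(s$values[(k + 1):1e4]) - mean(s$values[1:k])) - 2), 0.1)
  # variance doubling at mid-sample
  dgp_s2 <- changepoint_dgp(c(1, 0), par, arma_params(phi = 0.3, sigma2 = 2),
                            break_fraction = 0.5)
  s2 <- simulate_changepoint(dgp_s2, 1e4, seed = 46)
  ratio <- var(s2$values[5001:1e4]) / var(s2$values[1:5000])
  expect_lt(abs(ratio - 2), 0.15)
})

test_that("break index convention and input contracts hold", {
  par <- arma_params(phi = 0.3)
  dgp <- changepoint_dgp(c(1, 0), par, arma_params(phi = 0.5), break_fraction = 0.25)
  s <- simulate_changepoint(dgp, 201, seed = 47)
  expect_identical(s$true_break_index, as.integer(floor(201 * 0.25)))
  expect_error(changepoint_dgp(c(1, 0), par, arma_params(phi = 0.5),
                               break_fraction = 1.2), "strictly in")
  expect_error(changepoint_dgp(c(1, 0), par, arma_params(phi = 0.5)),
               "post_break must equal baseline")
  expect_error(simulate_changepoint(dgp, 10), ">= 20")
})

test_that("innovation distribution tags are standardized to unit variance", {
  for (d in c("t", "uniform")) {
    y <- simulate_arma(arma_params(sigma2 = 4), n = 5e4, seed = 48,
                       innovation = d)
    expect_lt(abs(var(y) / 4 - 1), 0.1)
  }
})

test_that("simulated series round-trip through the CSV fixture writer", {
  dgp <- changepoint_dgp(c(1, 0), arma_params(phi = 0.3),
                         arma_params(phi = 0.7), break_fraction = 0.5)
  s <- simulate_changepoint(dgp, 50, seed = 49)
  path <- file.path(tempdir(), "fixture.csv")
  write_simulated_series(s, path)
  expect_equal(read_series(path), s$values, tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$true_break_index, 25)
  expect_equal(meta$seed, 49)
  unlink(c(path, paste0(path, ".json")))
})
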