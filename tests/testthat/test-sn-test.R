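test_that("the end-to-end test is deterministic and internally consistent", {
  y <- simulate_arma(arma_params(phi = 0.3), n = 250, seed = 81)
  y[126:250] <- y[126:250] + 2
  t1 <- sn_cpt_test(y, order = c(1, 0), cal_reps = 500, seed = 5)
  t2 <- sn_cpt_test(y, order = c(1, 0), cal_reps = 500, seed = 5)
  expect_identical(t1$statistic, t2$statistic)
  expect_identical(t1$k_hat, t2$k_hat)
  expect_identical(t1$p_value, t2$p_value)
  expect_identical(t1$critical_value, t2$critical_value)
  # invariants of the result object
  expect_equal(t1$statistic, max(t1$profile$gn))
  expect_identical(t1$reject, t1$statistic > t1$critical_value)
  expect_identical(t1$residual_source, "qmle")
  expect_true(t1$p_value > 0 && t1$p_value <= 1)
  # a 2-sigma mid-sample level shift is overwhelming at n = 250
  expect_true(t1$reject)
  expect_lt(abs(t1$k_hat / t1$n - 0.5), 0.05)
})

test_that("a supplied calibration is honored and reused", {
  cal <- simulate_null_Tn(150, 400, seed = 82)
  y <- simulate_arma(arma_params(phi = 0.3), n = 150, seed = 83)
  tst <- sn_cpt_test(y, order = c(1, 0), calibration = cal)
  expect_identical(tst$critical_value, critical_value(cal, 0.05))
  expect_identical(tst$calibration$reps, 400L)
})

test_that("competitor statistics are attached on request", {
  y <- simulate_arma(arma_params(phi = 0.3), n = 200, seed = 84)
  tst <- sn_cpt_test(y, order = c(1, 0), cal_reps = 300, competitors = TRUE)
  expect_true(is.list(tst$competitor))
  expect_gte(tst$competitor$t_ls, 0)
  expect_gte(tst$competitor$t_max, 0)
})

test_that("results serialize to JSON and the profile to CSV", {
  y <- simulate_arma(arma_params(phi = 0.3), n = 150, seed = 85)
  tst <- sn_cpt_test(y, order = c(1, 0), cal_reps = 300)
  jf <- file.path(tempdir(), "res.json")
  pf <- file.path(tempdir(), "prof.csv")
  write_sn_result(tst, jf)
  write_gn_profile(tst, pf)
  back <- jsonlite::read_json(jf)
  expect_equal(back$statistic, tst$statistic, tolerance = 1e-12)
  expect_equal(back$k_hat, tst$k_hat)
  expect_equal(back$reject, tst$reject)
  prof <- read.csv(pf)
  expect_equal(prof$gn, tst$profile$gn, tolerance = 1e-12)
  unlink(c(jf, pf))
})

test_that("print, summary and plot methods run cleanly", {
  y <- simulate_arma(arma_params(phi = 0.3), n = 150, seed = 86)
  tst <- sn_cpt_test(y, order = c(1, 0), cal_reps = 300)
  expect_output(print(tst), "Self-normalized ARMA change-point test")
  expect_output(summary(tst), "Gn profile")
  pdf(NULL)
  expect_silent(plot(tst))
  dev.off()
})
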