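# Expensive shared objects (Monte Carlo calibrations) computed once per
# test run, on first use.

.test_cache <- new.env(parent = emptyenv())

cached <- function(name, compute) {
  if (is.null(.test_cache[[name]])) .test_cache[[name]] <- compute()
  .test_cache[[name]]
}

sn_cal_200 <- function() cached("sn_cal_200", function() {
  simulate_null_Tn(n = 200, reps = 10000, seed = 101)
})

sn_cal_500 <- function() cached("sn_cal_500", function() {
  simulate_null_Tn(n = 500, reps = 10000, seed = 101)
})

# one study cell under the full pipeline; rates come back with MC error
# sqrt(r(1-r)/reps)
study_cell <- function(order, n, post = NULL, frac = NULL, mu = 0,
                       reps = 1000, seed = 101) {
  base <- arma_params(phi = if (order[1] > 0) 0.3 else numeric(),
                      theta = if (order[2] > 0) 0.3 else numeric(),
                      sigma2 = 1)
  dgp <- if (is.null(post)) {
    changepoint_dgp(order, base)
  } else {
    changepoint_dgp(order, base, post, break_fraction = frac, mean_shift = mu)
  }
  cal <- if (n == 200) sn_cal_200() else sn_cal_500()
  sc <- scenario("cell", dgp, n = n, fit_order = order, reps = reps, seed = seed)
  run_scenario(sc, sn_null = cal, competitors = FALSE)
}
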