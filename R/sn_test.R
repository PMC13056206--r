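#' Self-normalized change-point test for ARMA time series
#'
#' The package's main entry point. Fits a zero-mean ARMA(p, q) model to the
#' series by Gaussian QMLE (or, optionally, the experimental SVR backend),
#' extracts the recursive residuals, scans the trimmed candidate window
#' with the self-normalized statistic, and calibrates the decision against
#' a Monte Carlo null distribution. The estimated break location `k_hat` is
#' the last index of the pre-break segment.
#'
#' When `calibration` is `NULL` the null distribution is simulated at the
#' observed series length with `cal_reps` i.i.d.-residual draws (the
#' statistic is invariant to residual scale and location, and refitting
#' changes its upper quantiles by well under the Monte Carlo error, so this
#' is the default route). Pass a precomputed [simulate_null_Tn()] /
#' [simulate_limit_functional()] object to reuse a calibration across
#' series.
#'
#' @param y numeric series (or anything [read_series()] returns).
#' @param order integer `c(p, q)` of the ARMA model to fit.
#' @param trim trimming pair `c(tau1, tau2)`; default (0.15, 0.85).
#' @param alpha significance level; default 0.05.
#' @param calibration optional [null_samples()] object.
#' @param cal_reps Monte Carlo draws for automatic calibration.
#' @param seed integer seed controlling the automatic calibration (and
#'   nothing else; the test itself is deterministic given the series).
#' @param backend residual backend: `"qmle"` (default) or `"svr"`.
#' @param demean subtract the sample mean before fitting? The model has no
#'   intercept, so this is off by default; enable it for real data whose
#'   level is far from zero.
#' @param competitors also compute the two benchmark score statistics?
#' @return Object of class `"sn_cpt_test"`: list with `statistic` (Tn),
#'   `k_hat`, `profile`, `critical_value`, `p_value`, `alpha`, `reject`,
#'   `n`, `trim`, `residual_source`, `order`, `fit`, `calibration`
#'   (provenance of the null samples), and optionally `competitor`.
#' @examples
#' y <- simulate_arma(arma_params(phi = 0.3), n = 300, seed = 7)
#' y[151:300] <- y[151:300] + 2
#' tst <- sn_cpt_test(y, order = c(1, 0), cal_reps = 500, seed = 1)
#' tst
#' @export
sn_cpt_test <- function(y, order = c(1L, 0L), trim = c(0.15, 0.85),
                        alpha = 0.05, calibration = NULL, cal_reps = 10000L,
                        seed = 1L, backend = c("qmle", "svr"),
                        demean = FALSE, competitors = FALSE) {
  series_name <- deparse(substitute(y))
  y <- check_numeric_series(y)
  order <- check_order(order)
  backend <- match.arg(backend)
  if (demean) y <- y - mean(y)
  fit <- NULL
  if (backend == "qmle") {
    fit <- fit_arma_qmle(y, order)
    if (!fit$converged) {
      warning("QMLE fit did not converge; test result may be unreliable")
    }
    e <- arma_residuals(y, fit$params)
  } else {
    e <- svr_residuals(y, order)
  }
  st <- sn_statistic(e, trim)
  if (is.null(calibration)) {
    calibration <- simulate_null_Tn(n = length(y), reps = cal_reps, trim = trim,
                                    seed = derive_seed(seed, 1L, 0L))
  }
  stopifnot(inherits(calibration, "sn_null_samples"))
  cv <- critical_value(calibration, alpha)
  pv <- p_value(st$statistic, calibration)
  out <- list(statistic = st$statistic, k_hat = st$k_hat,
              profile = st$profile, critical_value = cv, p_value = pv,
              alpha = alpha, reject = st$statistic > cv,
              n = st$n, trim = st$trim,
              residual_source = attr(e, "source") %||% backend,
              order = order, fit = fit,
              calibration = list(method = calibration$method,
                                 n_or_grid = calibration$n_or_grid,
                                 reps = calibration$reps,
                                 seed = calibration$seed),
              series_name = series_name)
  if (competitors) {
    out$competitor <- competitor_stats(y, e)
  }
  class(out) <- "sn_cpt_test"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sn_cpt_test <- function(x, ...) {
  cat("\n\tSelf-normalized ARMA change-point test\n\n")
  cat(sprintf("data:  %s (n = %d), ARMA(%d,%d) residuals [%s]\n",
              x$series_name, x$n, x$order[1], x$order[2], x$residual_source))
  cat(sprintf("Tn = %.4g, break estimate k-hat = %d (fraction %.3f)\n",
              x$statistic, x$k_hat, x$k_hat / x$n))
  cat(sprintf("%.4g%% critical value = %.4g  (MC, %s, reps = %d)\n",
              100 * x$alpha, x$critical_value, x$calibration$method,
              x$calibration$reps))
  cat(sprintf("p-value = %.4g\n", x$p_value))
  cat(if (x$reject) "=> reject no-change: structural break detected\n"
      else "=> no evidence against parameter constancy\n")
  invisible(x)
}

#' @export
summary.sn_cpt_test <- function(object, ...) {
  print(object)
  cat(sprintf("\nGn profile over k in [%d, %d] (trim %.2f/%.2f):\n",
              min(object$profile$k), max(object$profile$k),
              object$trim[1], object$trim[2]))
  print(summary(object$profile$gn))
  if (!is.null(object$fit)) {
    cat("\n"); print(object$fit)
  }
  if (!is.null(object$competitor)) {
    cat(sprintf("\nbenchmark statistics: T_ls = %.4g (k = %d), T_max = %.4g (k = %d)\n",
                object$competitor$t_ls, object$competitor$k_at_max_ls,
                object$competitor$t_max, object$competitor$k_at_max_max))
  }
  invisible(object)
}

#' @export
plot.sn_cpt_test <- function(x, ...) {
  plot(x$profile$k, x$profile$gn, type = "l",
       xlab = "candidate break index k", ylab = expression(G[n](k)),
       main = "Self-normalized change-point profile", ...)
  graphics::abline(h = x$critical_value, lty = 2)
  graphics::abline(v = x$k_hat, col = 2, lty = 3)
  invisible(x)
}

#' Serialize a test result to JSON
#'
#' Writes the scalar fields of an [sn_cpt_test()] result (and optionally
#' the Gn profile) as JSON; [write_gn_profile()] emits the profile alone as
#' a two-column CSV for plotting.
#'
#' @param result an `"sn_cpt_test"` object.
#' @param path output file path.
#' @param profile include the Gn profile in the JSON?
#' @return `path`, invisibly.
#' @export
write_sn_result <- function(result, path, profile = FALSE) {
  stopifnot(inherits(result, "sn_cpt_test"))
  out <- list(statistic = result$statistic, k_hat = result$k_hat,
              k_hat_fraction = result$k_hat / result$n,
              critical_value = result$critical_value,
              p_value = result$p_value, alpha = result$alpha,
              reject = result$reject, n = result$n,
              trim = result$trim, order = result$order,
              residual_source = result$residual_source,
              calibration = result$calibration)
  if (!is.null(result$competitor)) out$competitor <- result$competitor
  if (profile) out$profile <- result$profile
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sn_result
#' @export
write_gn_profile <- function(result, path) {
  stopifnot(inherits(result, "sn_cpt_test"))
  utils::write.csv(result$profile, path, row.names = FALSE)
  invisible(path)
}
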