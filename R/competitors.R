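#' Variance estimators for the benchmark score tests
#'
#' The two normalizers of the Lee-type score statistics:
#' `tau1_sq = mean((y - e)^2 * e^2)` and
#' `tau2_sq = mean(e^4) - mean(e^2)^2`,
#' where `e` are the model residuals and `y - e` the fitted part.
#'
#' @param y observed series.
#' @param resid residual vector of the same length.
#' @return List with `tau1_sq`, `tau2_sq` (both >= 0).
#' @export
variance_estimators <- function(y, resid) {
  y <- check_numeric_series(y)
  e <- check_numeric_series(resid, "resid")
  if (length(y) != length(e)) stop("`y` and `resid` must have equal length", call. = FALSE)
  list(tau1_sq = mean((y - e)^2 * e^2),
       tau2_sq = mean(e^4) - mean(e^2)^2)
}

#' Benchmark score-type change-point statistics
#'
#' The two SVR-residual score tests used as comparators: a likelihood-score
#' statistic
#' \deqn{\hat T_n^{ls} = \max_k \Big\{ \frac{|A(k)|^2}{n \hat\tau_{1,n}^2}
#'   + \frac{|B(k)|^2}{n \hat\tau_{2,n}^2} \Big\}}
#' and a maximum-type statistic
#' \deqn{\hat T_n^{max} = \max_k \max\Big\{ \frac{|A(k)|}{\sqrt n \hat\tau_{1,n}},
#'   \frac{|B(k)|}{\sqrt n \hat\tau_{2,n}} \Big\},}
#' with centered cumulative score processes
#' `A(k) = sum_{t<=k} (y_t - e_t) e_t - (k/n) sum_t (y_t - e_t) e_t` and
#' `B(k) = sum_{t<=k} e_t^2 - (k/n) sum_t e_t^2`, the maximum running over
#' the full range k = 1..n (these statistics are untrimmed). The scalings
#' `1/(n tau^2)` and `1/(sqrt(n) tau)` are the ones under which both
#' statistics are bounded in probability under the null.
#'
#' Structurally `A(n) = B(n) = 0` exactly. A zero variance estimator makes
#' the corresponding normalization undefined and is a degenerate-input
#' error (e.g. residuals equal to the series, so the fitted part vanishes).
#'
#' @param y observed series.
#' @param resid residual vector of the same length.
#' @return List with `t_ls`, `t_max`, `k_at_max_ls`, `k_at_max_max`,
#'   `tau1_sq`, `tau2_sq`.
#' @export
competitor_stats <- function(y, resid) {
  y <- check_numeric_series(y)
  e <- check_numeric_series(resid, "resid")
  n <- length(y)
  if (length(e) != n) stop("`y` and `resid` must have equal length", call. = FALSE)
  ve <- variance_estimators(y, e)
  if (ve$tau1_sq <= 0 || ve$tau2_sq <= 0) {
    stop("degenerate input: a variance estimator is zero", call. = FALSE)
  }
  a <- (y - e) * e
  b <- e^2
  k <- seq_len(n)
  A <- cumsum(a) - (k / n) * sum(a)
  B <- cumsum(b) - (k / n) * sum(b)
  ls_prof <- A^2 / (n * ve$tau1_sq) + B^2 / (n * ve$tau2_sq)
  max_prof <- pmax(abs(A) / (sqrt(n) * sqrt(ve$tau1_sq)),
                   abs(B) / (sqrt(n) * sqrt(ve$tau2_sq)))
  i_ls <- which.max(ls_prof)
  i_max <- which.max(max_prof)
  list(t_ls = ls_prof[i_ls], t_max = max_prof[i_max],
       k_at_max_ls = i_ls, k_at_max_max = i_max,
       tau1_sq = ve$tau1_sq, tau2_sq = ve$tau2_sq)
}

#' @rdname competitor_stats
#' @export
compute_T_ls <- function(y, resid) competitor_stats(y, resid)$t_ls

#' @rdname competitor_stats
#' @export
compute_T_max <- function(y, resid) competitor_stats(y, resid)$t_max

#' Null calibration of the benchmark statistics
#'
#' Simulates null ARMA series, refits by QMLE, extracts recursive
#' residuals and computes both score statistics per draw — the same
#' protocol as the self-normalized test's calibration, so size and power
#' comparisons are internally fair. (The direct i.i.d.-residual shortcut is
#' unavailable here: with `y = e` the fitted part vanishes and `tau1_sq`
#' degenerates, so calibration always refits.)
#'
#' @param n series length.
#' @param reps Monte Carlo draws (>= 100).
#' @param order,params null model to simulate and refit.
#' @param seed integer master seed.
#' @return `simulate_null_competitors()`: list with elements `ls` and
#'   `max`, each an [null_samples()] object. `calibrate_competitor()`
#'   returns the requested one.
#' @export
simulate_null_competitors <- function(n, reps, order, params, seed = 1L) {
  if (reps < 100) stop("`reps` must be at least 100", call. = FALSE)
  order <- check_order(order)
  stopifnot(inherits(params, "arma_params"))
  ls <- numeric(reps); mx <- numeric(reps)
  redo <- 0L
  for (r in seq_len(reps)) {
    res <- NULL
    tries <- 0L
    while (is.null(res)) {
      sr <- if (tries == 0L) derive_seed(seed, 13L, r)
            else derive_seed(seed, 53L, r * 64L + tries)
      y <- simulate_arma(params, n, seed = sr)
      fit <- fit_arma_qmle(y, order)
      if (fit$converged) {
        e <- arma_residuals(y, fit$params)
        res <- competitor_stats(y, e)
      } else {
        tries <- tries + 1L; redo <- redo + 1L
        if (tries > 25L) stop("persistent fit failure during competitor calibration")
      }
    }
    ls[r] <- res$t_ls; mx[r] <- res$t_max
  }
  trim <- c(0, 1)  # untrimmed statistics
  list(ls = null_samples(ls, "finite_sample", n, trim, seed, "ls", redo),
       max = null_samples(mx, "finite_sample", n, trim, seed, "max", redo))
}

#' @rdname simulate_null_competitors
#' @param statistic `"ls"` or `"max"`.
#' @export
calibrate_competitor <- function(statistic = c("ls", "max"), n, reps, order,
                                 params, seed = 1L) {
  statistic <- match.arg(statistic)
  simulate_null_competitors(n, reps, order, params, seed)[[statistic]]
}
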