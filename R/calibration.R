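#' Monte Carlo null samples of a change-point statistic
#'
#' Container carrying a vector of statistic draws together with full
#' provenance: which statistic, which route (finite-sample simulation or
#' the Brownian-bridge limit functional), the series length or path grid,
#' replication count, trimming and seed. Produced by [simulate_null_Tn()],
#' [simulate_limit_functional()] and [calibrate_competitor()]; consumed by
#' [critical_value()] and [p_value()].
#'
#' @param samples numeric vector of statistic draws.
#' @param method `"finite_sample"` or `"limit_functional"`.
#' @param n_or_grid series length or path-grid size.
#' @param trim trimming pair used.
#' @param seed seed used.
#' @param statistic_id `"sn"`, `"ls"` or `"max"`.
#' @param redo_count replicates that had to be redrawn (non-converged fits).
#' @return Object of class `"sn_null_samples"`.
#' @export
null_samples <- function(samples, method, n_or_grid, trim, seed, statistic_id,
                         redo_count = 0L) {
  stopifnot(is.numeric(samples), length(samples) >= 1L, all(is.finite(samples)),
            all(samples >= 0))
  structure(list(samples = as.numeric(samples), method = method,
                 n_or_grid = as.integer(n_or_grid), reps = length(samples),
                 trim = as.numeric(trim), seed = seed,
                 statistic_id = statistic_id, redo_count = as.integer(redo_count)),
            class = "sn_null_samples")
}

#' @export
print.sn_null_samples <- function(x, ...) {
  cat(sprintf("Null samples of '%s' statistic: %d draws, method = %s, %s = %d\n",
              x$statistic_id, x$reps, x$method,
              if (x$method == "limit_functional") "grid" else "n", x$n_or_grid))
  cat(sprintf("  trim (%.3g, %.3g), seed %s; 5%% critical value %.4g\n",
              x$trim[1], x$trim[2], format(x$seed),
              critical_value(x, 0.05)))
  if (x$redo_count > 0) cat("  redrawn replicates:", x$redo_count, "\n")
  invisible(x)
}

#' Simulate the finite-sample null distribution of Tn
#'
#' Draws independent null series, computes the trimmed-supremum statistic
#' for each, and returns the sample with provenance. With `refit = FALSE`
#' (the default calibration route) i.i.d. standard normal draws are used
#' directly as residuals — the statistic is scale invariant so the
#' innovation variance is irrelevant. With `refit = TRUE` each draw is a
#' simulated ARMA path of the given order and parameters that is refitted
#' by QMLE, with residuals extracted recursively, mirroring the full
#' pipeline; under the model's regularity conditions the two routes agree
#' asymptotically, and for moderate n their upper quantiles are within a
#' few percent.
#'
#' Each replicate runs under its own derived seed, so results do not depend
#' on how replicates are scheduled; non-converged refits are redrawn under
#' a fresh derived seed and counted in `redo_count`.
#'
#' @param n series length.
#' @param reps number of Monte Carlo draws (>= 100).
#' @param trim trimming pair.
#' @param seed integer master seed.
#' @param order,params model refitted when `refit = TRUE` (defaults: pure
#'   noise of the stated order, unit variance, zero coefficients).
#' @param refit logical; see above.
#' @return [null_samples()] object with `statistic_id = "sn"`.
#' @export
simulate_null_Tn <- function(n, reps, trim = c(0.15, 0.85), seed = 1L,
                             order = c(0L, 0L), params = NULL, refit = FALSE) {
  if (reps < 100) stop("`reps` must be at least 100", call. = FALSE)
  order <- check_order(order)
  if (refit && is.null(params)) {
    params <- arma_params(phi = rep(0, order[1]), theta = rep(0, order[2]),
                          sigma2 = 1)
  }
  samples <- numeric(reps)
  redo <- 0L
  ks <- trim_window(n, trim)
  for (r in seq_len(reps)) {
    if (!refit) {
      set.seed(derive_seed(seed, 11L, r))
      samples[r] <- max(sn_profile_engine(rnorm(n), ks))
      next
    }
    e <- NULL
    tries <- 0L
    while (is.null(e)) {
      sr <- if (tries == 0L) derive_seed(seed, 11L, r)
            else derive_seed(seed, 51L, r * 64L + tries)
      y <- simulate_arma(params, n, seed = sr)
      fit <- fit_arma_qmle(y, order)
      if (fit$converged) {
        e <- arma_residuals(y, fit$params)
      } else {
        tries <- tries + 1L; redo <- redo + 1L
        if (tries > 25L) stop("persistent fit failure during calibration")
      }
    }
    samples[r] <- max(sn_profile_engine(e, ks))
  }
  null_samples(samples, "finite_sample", n, trim, seed, "sn", redo)
}

#' Simulate the Brownian-bridge limit functional of Tn
#'
#' Draws three independent Brownian bridges B, B1, B2 on a uniform grid and
#' evaluates
#' \deqn{\sup_{s \in [\tau_1, \tau_2]}
#'   \frac{|B(s)|}{s(1-s)\sqrt{\int_0^s [B_1(u) - (u/s) B_1(s)]^2 du
#'     + \int_s^1 [B_2(u) - B_2(s)]^2 du}}}
#' — the null limit of the statistic, with the normalization factor
#' s(1-s) and the centered form of the second bridge integral taken from
#' the convergence derivation (the compact statement of the limit elsewhere
#' drops the factor and flips a sign; the derivation's final form is the
#' internally consistent one and is what this simulator implements).
#' Bridges are built as B(s) = W(s) - s W(1) from scaled random walks;
#' integrals are grid sums with the grid point at the right end of each
#' cell, the exact discrete analogue of the finite-sample sums.
#'
#' Note the three bridges are drawn independently, as the limit statement
#' specifies. In the finite-sample statistic the numerator and denominator
#' share one partial-sum path, so the two routes differ slightly even for
#' large n; their upper quantiles agree to within a few percent (see the
#' package vignette).
#'
#' @param grid path-grid size (>= 200).
#' @param reps number of Monte Carlo draws.
#' @param trim trimming pair.
#' @param seed integer master seed.
#' @return [null_samples()] object with `method = "limit_functional"`.
#' @export
simulate_limit_functional <- function(grid = 1000L, reps = 10000L,
                                      trim = c(0.15, 0.85), seed = 1L) {
  if (grid < 200) stop("`grid` must be at least 200", call. = FALSE)
  trim <- check_trim(trim)
  m <- as.integer(grid)
  u <- seq_len(m) / m
  du <- 1 / m
  idx <- which(u >= trim[1] & u <= trim[2])
  s <- u[idx]
  samples <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, 12L, r))
    W <- cumsum(rnorm(m)) / sqrt(m); B <- W - u * W[m]
    W <- cumsum(rnorm(m)) / sqrt(m); B1 <- W - u * W[m]
    W <- cumsum(rnorm(m)) / sqrt(m); B2 <- W - u * W[m]
    pB1sq <- cumsum(B1^2) * du; puB1 <- cumsum(u * B1) * du
    pu2 <- cumsum(u^2) * du
    pB2sq <- cumsum(B2^2) * du; pB2 <- cumsum(B2) * du
    I1 <- pB1sq[idx] - (2 * B1[idx] / s) * puB1[idx] + (B1[idx]^2 / s^2) * pu2[idx]
    I2 <- (pB2sq[m] - pB2sq[idx]) - 2 * B2[idx] * (pB2[m] - pB2[idx]) +
      B2[idx]^2 * (1 - s)
    samples[r] <- max(abs(B[idx]) / (s * (1 - s) * sqrt(pmax(I1 + I2, 0))))
  }
  null_samples(samples, "limit_functional", m, trim, seed, "sn")
}

#' Empirical critical value from null samples
#'
#' The (1 - alpha) empirical quantile using the ceiling order-statistic
#' convention: the sorted sample at index `ceiling((1 - alpha) * reps)`.
#' Conservative and fully reproducible.
#'
#' @param nullset an [null_samples()] object.
#' @param alpha significance level in (0, 1) with `reps * alpha >= 5`.
#' @return The critical value, a single number.
#' @examples
#' ns <- null_samples(1:100, "finite_sample", 100, c(.15, .85), 1, "sn")
#' critical_value(ns, 0.05)  # 95
#' @export
critical_value <- function(nullset, alpha) {
  stopifnot(inherits(nullset, "sn_null_samples"))
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  if (nullset$reps * alpha < 5) {
    stop("too few null samples for this alpha: need reps * alpha >= 5", call. = FALSE)
  }
  sort(nullset$samples)[ceiling((1 - alpha) * nullset$reps)]
}

#' Monte Carlo p-value with the add-one rule
#'
#' `(1 + #\{samples >= statistic\}) / (reps + 1)`: never exactly zero, and
#' exact under exchangeability of the observed statistic with the null
#' draws.
#'
#' @param statistic observed statistic value.
#' @param nullset an [null_samples()] object.
#' @return p-value in (0, 1].
#' @export
p_value <- function(statistic, nullset) {
  stopifnot(inherits(nullset, "sn_null_samples"), length(statistic) == 1L)
  (1 + sum(nullset$samples >= statistic)) / (nullset$reps + 1)
}

#' Persist and reload critical-value tables
#'
#' A critical-value table is a plain data.frame with columns
#' `statistic_id, tau1, tau2, alpha, n_or_grid, reps, seed, method,
#' critical_value`; `cv_table()` builds rows from a null-sample set, and
#' the write/read pair round-trips the table losslessly through CSV. A
#' small precomputed table for the default trimming ships with the package
#' (see [shipped_critical_values()]).
#'
#' @param nullset an [null_samples()] object.
#' @param alphas significance levels to tabulate.
#' @return `cv_table()`: a data.frame, one row per alpha.
#' @export
cv_table <- function(nullset, alphas = c(0.10, 0.05, 0.01)) {
  stopifnot(inherits(nullset, "sn_null_samples"))
  data.frame(statistic_id = nullset$statistic_id,
             tau1 = nullset$trim[1], tau2 = nullset$trim[2],
             alpha = alphas, n_or_grid = nullset$n_or_grid,
             reps = nullset$reps, seed = nullset$seed,
             method = nullset$method,
             critical_value = vapply(alphas, function(a) critical_value(nullset, a),
                                     numeric(1)))
}

#' @rdname cv_table
#' @param table a critical-value data.frame.
#' @param path CSV file path.
#' @export
write_critical_values <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cv_table
#' @export
read_critical_values <- function(path) {
  utils::read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}

#' @rdname cv_table
#' @details The shipped table was generated with
#'   `simulate_null_Tn(n, 50000, seed = 20260901)` for n in 200/500/1000 and
#'   `simulate_limit_functional(1000, 50000, seed = 20260901)`, trimming
#'   (0.15, 0.85); rerunning those calls reproduces it exactly.
#' @export
shipped_critical_values <- function() {
  read_critical_values(system.file("extdata", "critical_values.csv",
                                   package = "sncpt", mustWork = TRUE))
}
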