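#' ARMA parameter vector
#'
#' Bundles the AR coefficients, MA coefficients and innovation variance of a
#' (zero-mean) ARMA(p, q) model into a light container used throughout the
#' package. Stationarity and invertibility are *checked and flagged*, never
#' silently enforced: a non-stationary parameter set is legal input (e.g. to
#' study the test's behaviour under misspecification) but is worth knowing
#' about.
#'
#' @param phi numeric vector of AR coefficients (length p, possibly empty).
#' @param theta numeric vector of MA coefficients (length q, possibly empty).
#' @param sigma2 positive innovation variance.
#' @return An object of class `"arma_params"`: a list with elements `phi`,
#'   `theta`, `sigma2`.
#' @examples
#' p <- arma_params(phi = 0.3, theta = 0.3, sigma2 = 1)
#' is_stationary(p)
#' @export
arma_params <- function(phi = numeric(), theta = numeric(), sigma2 = 1) {
  phi <- as.numeric(phi)
  theta <- as.numeric(theta)
  if (length(sigma2) != 1L || !is.finite(sigma2) || sigma2 <= 0) {
    stop("`sigma2` must be a single positive number", call. = FALSE)
  }
  if (anyNA(phi) || anyNA(theta)) stop("coefficients must be finite", call. = FALSE)
  structure(list(phi = phi, theta = theta, sigma2 = as.numeric(sigma2)),
            class = "arma_params")
}

#' @export
print.arma_params <- function(x, ...) {
  cat("ARMA parameters: p =", length(x$phi), " q =", length(x$theta), "\n")
  if (length(x$phi)) cat("  phi:   ", paste(signif(x$phi, 4), collapse = " "), "\n")
  if (length(x$theta)) cat("  theta: ", paste(signif(x$theta, 4), collapse = " "), "\n")
  cat("  sigma2:", signif(x$sigma2, 4), "\n")
  if (!is_stationary(x)) cat("  (AR polynomial root on/inside unit circle: non-stationary)\n")
  if (!is_invertible(x)) cat("  (MA polynomial root on/inside unit circle: non-invertible)\n")
  invisible(x)
}

poly_roots_outside <- function(coefs) {
  if (!length(coefs)) return(TRUE)
  # characteristic polynomial 1 - c1 z - ... - cp z^p (AR convention);
  # callers pass +theta for the MA polynomial 1 + t1 z + ... via negation
  r <- polyroot(c(1, -coefs))
  all(Mod(r) > 1 + 1e-8)
}

#' @rdname arma_params
#' @param params an `arma_params` object.
#' @export
is_stationary <- function(params) poly_roots_outside(params$phi)

#' @rdname arma_params
#' @export
is_invertible <- function(params) poly_roots_outside(-params$theta)

#' Fit an ARMA(p, q) model by Gaussian quasi-maximum likelihood
#'
#' Thin wrapper around [stats::arima()] for the zero-mean ARMA(p, q) model
#' (`include.mean = FALSE`). Estimation failures and convergence problems
#' are recorded in the returned `converged` flag, never hidden: a fit that
#' did not converge still returns (possibly `NA`) estimates and it is the
#' caller's decision what to do with them.
#'
#' For the degenerate order (0, 0) no optimization is run: `phi` and `theta`
#' are empty and `sigma2` is the mean squared deviation of the series about
#' its sample mean.
#'
#' @param y numeric series, length at least `10 * (p + q + 1)`.
#' @param order integer vector `c(p, q)`.
#' @param method optimization route passed to [stats::arima()];
#'   `"CSS-ML"` (conditional-sum-of-squares start, then full Gaussian
#'   likelihood) is the default.
#' @return An object of class `"arma_qmle_fit"`: list with `params`
#'   ([arma_params]), `order`, `loglik`, `converged`, `n_used`.
#' @examples
#' y <- simulate_arma(arma_params(phi = 0.5), n = 400, seed = 1)
#' fit_arma_qmle(y, order = c(1, 0))
#' @export
fit_arma_qmle <- function(y, order, method = c("CSS-ML", "ML", "CSS")) {
  y <- check_numeric_series(y)
  order <- check_order(order)
  method <- match.arg(method)
  p <- order[1]; q <- order[2]
  n <- length(y)
  if (n < 10 * (p + q + 1)) {
    stop(sprintf("series too short for order (%d,%d): need n >= %d, got %d",
                 p, q, 10 * (p + q + 1), n), call. = FALSE)
  }
  if (p == 0 && q == 0) {
    s2 <- mean((y - mean(y))^2)
    fit <- list(params = arma_params(sigma2 = s2),
                order = order,
                loglik = sum(dnorm(y, mean(y), sqrt(s2), log = TRUE)),
                converged = TRUE, n_used = n)
    class(fit) <- "arma_qmle_fit"
    return(fit)
  }
  warned <- FALSE
  res <- tryCatch(
    withCallingHandlers(
      stats::arima(y, order = c(p, 0L, q), include.mean = FALSE, method = method),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    ),
    error = function(e) e
  )
  if (inherits(res, "error")) {
    # keep the (NA) parameter slots so the shape of the result is stable
    fit <- list(params = structure(list(phi = rep(NA_real_, p),
                                        theta = rep(NA_real_, q),
                                        sigma2 = NA_real_),
                                   class = "arma_params"),
                order = order, loglik = NA_real_, converged = FALSE, n_used = n,
                message = conditionMessage(res))
    class(fit) <- "arma_qmle_fit"
    return(fit)
  }
  cf <- unname(res$coef)
  phi <- if (p > 0) cf[seq_len(p)] else numeric()
  theta <- if (q > 0) cf[p + seq_len(q)] else numeric()
  fit <- list(params = arma_params(phi = phi, theta = theta, sigma2 = res$sigma2),
              order = order, loglik = res$loglik,
              converged = (res$code == 0) && !warned, n_used = n)
  class(fit) <- "arma_qmle_fit"
  fit
}

#' @export
print.arma_qmle_fit <- function(x, ...) {
  cat(sprintf("ARMA(%d,%d) Gaussian QMLE fit, n = %d\n",
              x$order[1], x$order[2], x$n_used))
  print(x$params)
  cat("  log-likelihood:", signif(x$loglik, 6),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' @export
coef.arma_qmle_fit <- function(object, ...) {
  c(if (length(object$params$phi)) stats::setNames(object$params$phi, paste0("phi", seq_along(object$params$phi))),
    if (length(object$params$theta)) stats::setNames(object$params$theta, paste0("theta", seq_along(object$params$theta))),
    sigma2 = object$params$sigma2)
}

#' Recursive ARMA residuals with zero pre-sample values
#'
#' Computes the one-sided residual recursion
#' \deqn{\hat\varepsilon_t = y_t - \sum_{i=1}^p \hat\phi_i y_{t-i}
#'       - \sum_{j=1}^q \hat\theta_j \hat\varepsilon_{t-j}}
#' for t = 1..n with the convention that y and the residuals are zero for
#' t <= 0. These are exactly the residuals the self-normalized statistic is
#' defined on — no backcasting and no Kalman smoothing, even when the fit
#' itself used the exact likelihood.
#'
#' @param y numeric series.
#' @param params an [arma_params] object (the fitted coefficients).
#' @param order optional `c(p, q)`; when given it is checked against the
#'   dimensions of `params` and a mismatch is an error.
#' @return Numeric vector of residuals, same length as `y`, with attribute
#'   `source = "qmle"` (provenance tag; [svr_residuals()] tags `"svr"`).
#' @examples
#' arma_residuals(c(1, 0, 0), arma_params(phi = 0.5))  # (1, -0.5, 0)
#' @export
arma_residuals <- function(y, params, order = NULL) {
  y <- check_numeric_series(y)
  if (!inherits(params, "arma_params")) stop("`params` must be an arma_params object", call. = FALSE)
  if (!is.null(order)) {
    order <- check_order(order)
    if (length(params$phi) != order[1] || length(params$theta) != order[2]) {
      stop(sprintf("params dimension (p=%d, q=%d) does not match order (%d,%d)",
                   length(params$phi), length(params$theta), order[1], order[2]),
           call. = FALSE)
    }
  }
  if (anyNA(params$phi) || anyNA(params$theta)) {
    stop("params contain NA coefficients (non-converged fit?)", call. = FALSE)
  }
  n <- length(y)
  a <- y
  for (i in seq_along(params$phi)) {
    if (i < n) a[(i + 1):n] <- a[(i + 1):n] - params$phi[i] * y[1:(n - i)]
  }
  e <- if (length(params$theta)) {
    as.numeric(stats::filter(a, -params$theta, method = "recursive"))
  } else {
    a
  }
  attr(e, "source") <- "qmle"
  e
}

#' @rdname arma_residuals
#' @param object an `"arma_qmle_fit"` object.
#' @param ... unused.
#' @export
residuals.arma_qmle_fit <- function(object, y, ...) {
  arma_residuals(y, object$params, object$order)
}
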