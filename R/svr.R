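#' Support-vector-regression residuals (experimental backend)
#'
#' One-step-ahead epsilon-insensitive support vector regression of y_t on
#' its p lagged observations, with radial-basis kernel. When q > 0 the MA
#' structure is approximated by also feeding q lags of the residuals from
#' the previous pass and iterating; the first pass starts from zero residual
#' lags, matching the zero pre-sample convention of [arma_residuals()].
#' Residuals are observed minus fitted values. For order (0, 0) the
#' residuals are the series itself, exactly the QMLE convention, so the two
#' backends are interchangeable downstream.
#'
#' Hyperparameters left `NULL` are chosen from a small fixed grid
#' (cost in \{1, 10\}, epsilon in \{0.01, 0.1\}) by rolling-origin
#' validation: fit on the first 75% of rows, score one-step MSE on the last
#' 25%, keep the minimizer. This is deliberately modest — the backend exists
#' for exploring nonlinear fits, the default inference route is QMLE.
#'
#' @param y numeric series.
#' @param order integer vector `c(p, q)`.
#' @param cost,gamma,epsilon optional SVR hyperparameters; `NULL` selects
#'   by the validation grid (gamma defaults to 1/ncol as in e1071).
#' @param iterations number of residual-lag refinement passes when q > 0.
#' @return Numeric residual vector, length of `y`, attribute `source = "svr"`.
#' @seealso [arma_residuals()] for the default backend.
#' @export
svr_residuals <- function(y, order, cost = NULL, gamma = NULL, epsilon = NULL,
                          iterations = 2L) {
  y <- check_numeric_series(y)
  order <- check_order(order)
  p <- order[1]; q <- order[2]
  n <- length(y)
  if (p == 0 && q == 0) {
    e <- y
    attr(e, "source") <- "svr"
    return(e)
  }
  if (n < max(p, q) + 20L) {
    stop(sprintf("series too short for SVR lag construction: need n >= %d",
                 max(p, q) + 20L), call. = FALSE)
  }
  if (!requireNamespace("e1071", quietly = TRUE)) {
    stop("the SVR backend requires the e1071 package", call. = FALSE)
  }
  if (sd(y) == 0) {
    # degenerate regression: fitted values are the constant itself
    e <- rep(0, n)
    attr(e, "source") <- "svr"
    return(e)
  }

  lag_mat <- function(v, lags) {
    # zero-padded lag matrix, one row per t = 1..n
    out <- matrix(0, n, lags)
    for (i in seq_len(lags)) out[(i + 1):n, i] <- v[1:(n - i)]
    out
  }

  fit_pass <- function(e_prev, cost, gamma, epsilon, train_idx = NULL) {
    X <- cbind(if (p > 0) lag_mat(y, p),
               if (q > 0) lag_mat(e_prev, q))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
    # constant regressors (e.g. the zero residual lags of the first pass)
    # carry no information and break e1071's scaling
    keep <- apply(X, 2, function(col) diff(range(col)) > 0)
    if (!any(keep)) return(y - mean(y))
    X <- X[, keep, drop = FALSE]
    idx <- if (is.null(train_idx)) seq_len(n) else train_idx
    m <- e1071::svm(x = X[idx, , drop = FALSE], y = y[idx],
                    kernel = "radial", type = "eps-regression",
                    cost = cost, epsilon = epsilon,
                    gamma = if (is.null(gamma)) 1 / ncol(X) else gamma,
                    scale = TRUE)
    y - as.numeric(stats::predict(m, X))
  }

  if (is.null(cost) || is.null(epsilon)) {
    grid <- expand.grid(cost = if (is.null(cost)) c(1, 10) else cost,
                        epsilon = if (is.null(epsilon)) c(0.01, 0.1) else epsilon)
    split <- floor(0.75 * n)
    score <- vapply(seq_len(nrow(grid)), function(i) {
      e <- fit_pass(rep(0, n), grid$cost[i], gamma, grid$epsilon[i],
                    train_idx = seq_len(split))
      mean(e[(split + 1):n]^2)
    }, numeric(1))
    best <- which.min(score)
    cost <- grid$cost[best]
    epsilon <- grid$epsilon[best]
  }

  e <- rep(0, n)
  passes <- if (q > 0) max(1L, as.integer(iterations)) else 1L
  for (it in seq_len(passes)) e <- fit_pass(e, cost, gamma, epsilon)
  attr(e, "source") <- "svr"
  e
}
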