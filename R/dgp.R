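#' Simulate a stationary ARMA(p, q) path
#'
#' Seeded, reproducible ARMA simulation by direct recursion. `burn_in`
#' leading observations are generated and discarded so the retained path is
#' approximately stationary; the default of 200 is ample for the moderately
#' persistent models studied here.
#'
#' @param params an [arma_params] object. A non-stationary or
#'   non-invertible parameter set triggers a warning, not an error.
#' @param n number of retained observations (>= 1).
#' @param seed optional integer seed; same seed, same path.
#' @param burn_in discarded leading observations (default 200).
#' @param innovation innovation distribution tag: `"normal"` (default),
#'   `"t"` (t with 5 df, scaled to unit variance) or `"uniform"` (scaled to
#'   unit variance). `sigma2` in `params` sets the variance in every case.
#' @return Numeric vector of length `n`.
#' @examples
#' y <- simulate_arma(arma_params(phi = 0.5), n = 500, seed = 42)
#' @export
simulate_arma <- function(params, n, seed = NULL, burn_in = 200L,
                          innovation = c("normal", "t", "uniform")) {
  if (!inherits(params, "arma_params")) stop("`params` must be an arma_params object", call. = FALSE)
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  innovation <- match.arg(innovation)
  if (!is_stationary(params)) warning("AR polynomial is not stationary")
  if (!is_invertible(params)) warning("MA polynomial is not invertible")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n); burn_in <- as.integer(burn_in)
  m <- burn_in + n
  e <- sqrt(params$sigma2) * draw_innovations(m, innovation)
  y <- arma_recursion(e, params, params, kabs = m)
  y[(burn_in + 1):m]
}

# y_t = sum_i phi_i y_{t-i} + e_t + sum_j theta_j e_{t-j}, zero pre-sample
# values, parameters switching from `pre` to `post` after index kabs. One
# shared code path serves the no-break case (kabs = length(e)) so that a
# null change-point specification reproduces simulate_arma() bit for bit.
# The AR recursion runs segment-wise through stats::filter, the post-break
# segment seeded with the last pre-break values so the state carries across
# the break without a reset; MA lags index the full innovation vector, so
# they cross the break too.
arma_recursion <- function(e, pre, post, kabs) {
  m <- length(e)
  ma_sum <- function(theta, idx) {
    x <- e[idx]
    for (j in seq_along(theta)) {
      src <- idx - j
      ok <- src >= 1L
      x[ok] <- x[ok] + theta[j] * e[src[ok]]
    }
    x
  }
  k1 <- min(kabs, m)
  x1 <- ma_sum(pre$theta, seq_len(k1))
  y1 <- if (length(pre$phi)) {
    as.numeric(stats::filter(x1, pre$phi, method = "recursive"))
  } else x1
  if (k1 >= m) return(y1)
  idx2 <- (k1 + 1L):m
  x2 <- ma_sum(post$theta, idx2)
  p <- length(post$phi)
  y2 <- if (p > 0) {
    init <- c(rev(y1), rep(0, p))[seq_len(p)]  # y[k1], y[k1-1], ... zero-padded
    as.numeric(stats::filter(x2, post$phi, method = "recursive", init = init))
  } else x2
  c(y1, y2)
}

#' Specify a single-break ARMA data-generating process
#'
#' Describes the synthetic designs used in the size/power studies: a
#' baseline parameter vector, an optional post-break parameter vector, an
#' optional break location (as a sample fraction) and an optional additive
#' post-break mean shift applied to the observations. With
#' `break_fraction = NULL` the process is the null model and `post_break` /
#' `mean_shift` must describe no change.
#'
#' @param order integer `c(p, q)` shared by both regimes.
#' @param baseline [arma_params] before the break.
#' @param post_break [arma_params] after the break (default: equal to
#'   `baseline`).
#' @param break_fraction break location as a fraction in (0, 1), or `NULL`
#'   for no break; the break index is `floor(n * break_fraction)`, the last
#'   index of the pre-break regime.
#' @param mean_shift additive shift applied to observations after the break
#'   (0 for none).
#' @param innovation innovation distribution tag, see [simulate_arma()].
#' @param burn_in discarded leading observations.
#' @return Object of class `"changepoint_dgp"`.
#' @examples
#' dgp <- changepoint_dgp(c(1, 0), arma_params(phi = 0.3),
#'                        arma_params(phi = 0.5), break_fraction = 0.5)
#' @export
changepoint_dgp <- function(order, baseline, post_break = baseline,
                            break_fraction = NULL, mean_shift = 0,
                            innovation = "normal", burn_in = 200L) {
  order <- check_order(order)
  for (pp in list(baseline, post_break)) {
    if (!inherits(pp, "arma_params")) stop("params must be arma_params objects", call. = FALSE)
    if (length(pp$phi) != order[1] || length(pp$theta) != order[2]) {
      stop("params dimensions must match `order`", call. = FALSE)
    }
  }
  if (is.null(break_fraction)) {
    if (!identical(unclass(baseline), unclass(post_break)) || mean_shift != 0) {
      stop("without a break_fraction, post_break must equal baseline and mean_shift must be 0",
           call. = FALSE)
    }
  } else {
    if (length(break_fraction) != 1L || !is.finite(break_fraction) ||
        break_fraction <= 0 || break_fraction >= 1) {
      stop("`break_fraction` must lie strictly in (0, 1)", call. = FALSE)
    }
  }
  structure(list(order = order, baseline = baseline, post_break = post_break,
                 break_fraction = break_fraction,
                 mean_shift = as.numeric(mean_shift),
                 innovation = innovation, burn_in = as.integer(burn_in)),
            class = "changepoint_dgp")
}

#' @export
print.changepoint_dgp <- function(x, ...) {
  cat(sprintf("Change-point DGP: ARMA(%d,%d)\n", x$order[1], x$order[2]))
  cat("baseline:\n"); print(x$baseline)
  if (is.null(x$break_fraction)) {
    cat("no break (null model)\n")
  } else {
    cat(sprintf("break at fraction %.3g; post-break:\n", x$break_fraction))
    print(x$post_break)
    if (x$mean_shift != 0) cat("post-break mean shift:", x$mean_shift, "\n")
  }
  invisible(x)
}

#' Simulate a series with (at most) one structural break
#'
#' Observations up to the break index are generated under the baseline
#' parameters, later ones under the post-break parameters. The recursion
#' state (lagged observations and innovations) carries across the break —
#' there is no reset — so a no-change specification reproduces
#' [simulate_arma()] exactly under the same seed. The mean shift, when
#' present, is added to the post-break observations after generation (it
#' shifts the observed level, not the innovations).
#'
#' @param dgp a [changepoint_dgp()] specification.
#' @param n retained series length (>= 20).
#' @param seed optional integer seed.
#' @return Object of class `"simulated_series"`: list with `values`
#'   (length n), `true_break_index` (`floor(n * break_fraction)` or `NULL`),
#'   `seed`, `dgp`.
#' @examples
#' dgp <- changepoint_dgp(c(1, 0), arma_params(phi = 0.3),
#'                        arma_params(phi = 0.7), break_fraction = 0.5)
#' s <- simulate_changepoint(dgp, n = 200, seed = 1)
#' @export
simulate_changepoint <- function(dgp, n, seed = NULL) {
  if (!inherits(dgp, "changepoint_dgp")) stop("`dgp` must be a changepoint_dgp object", call. = FALSE)
  if (length(n) != 1L || !is.finite(n) || n < 20) stop("`n` must be >= 20", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  burn <- dgp$burn_in
  m <- burn + n
  kstar <- if (is.null(dgp$break_fraction)) NULL else as.integer(floor(n * dgp$break_fraction))
  # absolute index of the last pre-break observation in the extended path
  kabs <- if (is.null(kstar)) m else burn + kstar
  z <- draw_innovations(m, dgp$innovation)
  s0 <- sqrt(dgp$baseline$sigma2)
  e <- s0 * z
  if (kabs < m) {
    s1 <- sqrt(dgp$post_break$sigma2)
    e[(kabs + 1):m] <- s1 * z[(kabs + 1):m]
  }
  y <- arma_recursion(e, dgp$baseline, dgp$post_break, kabs)
  out <- y[(burn + 1):m]
  if (!is.null(kstar) && dgp$mean_shift != 0 && kstar < n) {
    out[(kstar + 1):n] <- out[(kstar + 1):n] + dgp$mean_shift
  }
  structure(list(values = out, true_break_index = kstar, seed = seed, dgp = dgp),
            class = "simulated_series")
}

#' @export
print.simulated_series <- function(x, ...) {
  cat(sprintf("Simulated series: n = %d, break index = %s\n",
              length(x$values),
              if (is.null(x$true_break_index)) "none" else x$true_break_index))
  invisible(x)
}

#' Write a simulated series to CSV with a JSON provenance sidecar
#'
#' The CSV holds a single `value` column; the sidecar (`<path>.json`)
#' records the seed, the DGP specification and the true break index, enough
#' to regenerate the fixture exactly.
#'
#' @param sim a `"simulated_series"` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_simulated_series <- function(sim, path) {
  stopifnot(inherits(sim, "simulated_series"))
  utils::write.csv(data.frame(value = sim$values), path, row.names = FALSE)
  meta <- list(seed = sim$seed,
               true_break_index = sim$true_break_index,
               n = length(sim$values),
               order = sim$dgp$order,
               baseline = unclass(sim$dgp$baseline),
               post_break = unclass(sim$dgp$post_break),
               break_fraction = sim$dgp$break_fraction,
               mean_shift = sim$dgp$mean_shift,
               innovation = sim$dgp$innovation,
               burn_in = sim$dgp$burn_in)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
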