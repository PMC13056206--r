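# Internal helpers shared across modules.

# Deterministic per-replicate seed derivation. Streams keep calibration,
# competitor calibration, scenario replicates and redraws on disjoint seed
# ranges so no two purposes ever share randomness; the result stays inside
# the 32-bit integer range R's set.seed() accepts. Arithmetic is done in
# doubles (exact below 2^53).
derive_seed <- function(seed, stream, r) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 1000003 +
                as.numeric(stream) * 100000007 +
                as.numeric(r)) %% 2147483647)
}

# Standardized innovation sampler: unit variance for every tag so that
# sigma2 alone sets the innovation scale.
draw_innovations <- function(m, dist = c("normal", "t", "uniform")) {
  dist <- match.arg(dist)
  switch(dist,
    normal  = rnorm(m),
    t       = rt(m, df = 5) / sqrt(5 / 3),
    uniform = runif(m, -sqrt(3), sqrt(3))
  )
}

check_numeric_series <- function(y, what = "series") {
  if (!is.numeric(y) || length(y) == 0L) {
    stop(sprintf("`%s` must be a non-empty numeric vector", what), call. = FALSE)
  }
  if (!all(is.finite(y))) {
    stop(sprintf("`%s` contains non-finite values", what), call. = FALSE)
  }
  invisible(as.numeric(y))
}

check_order <- function(order) {
  if (length(order) != 2L || any(!is.finite(order)) || any(order < 0) ||
      any(order != floor(order))) {
    stop("`order` must be two non-negative integers c(p, q)", call. = FALSE)
  }
  as.integer(order)
}

check_trim <- function(trim) {
  if (length(trim) != 2L || any(!is.finite(trim)) ||
      !(0 < trim[1] && trim[1] < trim[2] && trim[2] < 1)) {
    stop("`trim` must satisfy 0 < tau1 < tau2 < 1", call. = FALSE)
  }
  as.numeric(trim)
}
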