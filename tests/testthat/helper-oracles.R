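# Independent literal-transcription oracles, deliberately written with
# plain loops and no package internals, used to cross-check the optimized
# implementations.

oracle_residuals <- function(y, phi, theta) {
  n <- length(y)
  e <- numeric(n)
  for (t in seq_len(n)) {
    acc <- y[t]
    for (i in seq_along(phi)) if (t > i) acc <- acc - phi[i] * y[t - i]
    for (j in seq_along(theta)) if (t > j) acc <- acc - theta[j] * e[t - j]
    e[t] <- acc
  }
  e
}

oracle_gn <- function(e, k) {
  n <- length(e)
  m1 <- mean(e[1:k])
  m2 <- mean(e[(k + 1):n])
  num <- n * abs(m1 - m2)
  ss <- 0
  for (t in 1:k) ss <- ss + sum(e[1:t] - m1)^2
  for (t in (k + 1):n) ss <- ss + sum(e[(k + 1):t] - m2)^2
  den <- sqrt(ss / n)
  if (den == 0) return(if (num == 0) 0 else Inf)
  num / den
}

oracle_competitors <- function(y, e) {
  n <- length(y)
  tau1 <- sum((y - e)^2 * e^2) / n
  tau2 <- sum(e^4) / n - (sum(e^2) / n)^2
  t_ls <- -Inf
  t_max <- -Inf
  for (k in 1:n) {
    A <- sum((y[1:k] - e[1:k]) * e[1:k]) - (k / n) * sum((y - e) * e)
    B <- sum(e[1:k]^2) - (k / n) * sum(e^2)
    ls <- abs(A)^2 / (n * tau1) + abs(B)^2 / (n * tau2)
    mx <- max(abs(A) / (sqrt(n) * sqrt(tau1)), abs(B) / (sqrt(n) * sqrt(tau2)))
    if (ls > t_ls) t_ls <- ls
    if (mx > t_max) t_max <- mx
  }
  list(t_ls = t_ls, t_max = t_max)
}
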