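#' Segment mean of a residual series
#'
#' Arithmetic mean of residuals over the inclusive 1-based index range
#' j..k. All index conventions in this package are 1-based with inclusive
#' segment ends.
#'
#' @param resid numeric residual vector.
#' @param j,k segment bounds, 1 <= j <= k <= n.
#' @return The mean of `resid[j:k]`.
#' @export
segment_mean <- function(resid, j, k) {
  n <- length(resid)
  if (j < 1 || k > n || j > k) stop("require 1 <= j <= k <= n", call. = FALSE)
  mean(resid[j:k])
}

#' Within-segment centered partial-sum process
#'
#' For the segment j..k, returns S_t = sum_{h=j}^{t} (e_h - mean(e[j:k]))
#' for t = j..k. The final entry is zero to machine precision (sum of
#' deviations from the segment mean).
#'
#' @inheritParams segment_mean
#' @return Numeric vector of length `k - j + 1`.
#' @export
partial_sum_process <- function(resid, j, k) {
  n <- length(resid)
  if (j < 1 || k > n || j > k) stop("require 1 <= j <= k <= n", call. = FALSE)
  seg <- resid[j:k]
  cumsum(seg - mean(seg))
}

#' Self-normalized statistic at a single candidate break
#'
#' Evaluates
#' \deqn{G_n(k) = \frac{n\,|\bar\varepsilon_{1,k} - \bar\varepsilon_{k+1,n}|}
#'   {\big[n^{-1}\big(\sum_{t=1}^{k} S_t^2(1,k) +
#'    \sum_{t=k+1}^{n} S_t^2(k+1,n)\big)\big]^{1/2}}}
#' by direct transcription of its definition: the numerator contrasts the
#' pre- and post-k residual means, the denominator self-normalizes by the
#' within-segment centered partial sums, so no long-run variance estimate
#' enters. When the denominator is exactly zero (both segments constant)
#' with a positive numerator the value is `+Inf` with a warning — perfect
#' within-segment constancy is infinitely strong evidence under this
#' statistic; a zero numerator with zero denominator gives 0.
#'
#' @param resid numeric residual vector.
#' @param k candidate break index, 1 <= k < n.
#' @return `Gn(k)`, a non-negative number (possibly `+Inf`).
#' @seealso [sn_statistic()] for the full scan; the two agree exactly.
#' @examples
#' sn_gn(c(1, 2, 3, 4), 2)  # 22.62742
#' @export
sn_gn <- function(resid, k) {
  n <- length(resid)
  if (k < 1 || k >= n) stop("require 1 <= k < n", call. = FALSE)
  num <- n * abs(segment_mean(resid, 1, k) - segment_mean(resid, k + 1, n))
  s1 <- partial_sum_process(resid, 1, k)
  s2 <- partial_sum_process(resid, k + 1, n)
  den <- sqrt((sum(s1^2) + sum(s2^2)) / n)
  if (den == 0) {
    if (num == 0) return(0)
    warning("degenerate denominator at k = ", k, ": both segments constant; Gn = Inf")
    return(Inf)
  }
  num / den
}

# O(1)-per-candidate profile using prefix-sum algebra. With C_t = cumsum(e):
#   S_t(1,k)   = C_t - (t/k) C_k
#   S_t(k+1,n) = (C_t - C_k) - ((t-k)/(n-k)) (C_n - C_k)
# and the squared sums expand into prefix sums of C^2, tC, C, t^2.
sn_profile_engine <- function(e, ks) {
  n <- length(e)
  C <- cumsum(e)
  t <- seq_len(n)
  P1 <- cumsum(C); P2 <- cumsum(C^2); Pt <- cumsum(t * C); st2 <- cumsum(t^2)
  Cn <- C[n]
  k <- ks
  Q1 <- P2[k] - (2 * C[k] / k) * Pt[k] + (C[k]^2 / k^2) * st2[k]
  mpost <- (Cn - C[k]) / (n - k)
  sumD2 <- (P2[n] - P2[k]) - 2 * C[k] * (P1[n] - P1[k]) + (n - k) * C[k]^2
  sumtD <- ((Pt[n] - Pt[k]) - k * (P1[n] - P1[k])) -
    C[k] * (n - k) * (n - k + 1) / 2
  sumr2 <- (n - k) * (n - k + 1) * (2 * (n - k) + 1) / 6
  Q2 <- sumD2 - 2 * mpost * sumtD + mpost^2 * sumr2
  num <- n * abs(C[k] / k - mpost)
  den <- sqrt(pmax(Q1 + Q2, 0) / n)
  gn <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
  if (any(is.infinite(gn))) {
    warning("degenerate denominator: constant segments at some candidates; Gn = Inf")
  }
  gn
}

trim_window <- function(n, trim) {
  trim <- check_trim(trim)
  k_lo <- ceiling(n * trim[1])
  k_hi <- floor(n * trim[2])
  if (k_lo < 2 || k_hi > n - 2 || k_lo > k_hi) {
    nmin <- 4
    while (TRUE) {
      lo <- ceiling(nmin * trim[1]); hi <- floor(nmin * trim[2])
      if (lo >= 2 && hi <= nmin - 2 && lo <= hi) break
      nmin <- nmin + 1
      if (nmin > 10000) break
    }
    stop(sprintf(
      "series too short for trimming window (%.3g, %.3g): need n >= %d, got %d",
      trim[1], trim[2], nmin, n), call. = FALSE)
  }
  k_lo:k_hi
}

#' Scan the trimmed window: Gn profile, supremum and break estimate
#'
#' Evaluates Gn(k) for every candidate k in the trimmed window
#' `ceiling(n*tau1) .. floor(n*tau2)` (each candidate leaves at least two
#' observations per segment), and returns the supremum statistic Tn
#' together with the break-location estimate k-hat, the smallest k
#' attaining the maximum. The scan uses cumulative-sum algebra with O(1)
#' work per candidate after an O(n) setup; it agrees exactly with repeated
#' calls to [sn_gn()].
#'
#' k-hat indexes the *last* observation of the pre-break segment.
#'
#' @param resid numeric residual vector.
#' @param trim numeric `c(tau1, tau2)`, 0 < tau1 < tau2 < 1; the defaults
#'   (0.15, 0.85) keep at least 15% of the sample in each segment.
#' @return List with `statistic` (Tn), `k_hat`, `profile` (data.frame with
#'   columns `k`, `gn`), `trim`, `n`.
#' @examples
#' e <- rnorm(100)
#' sn_statistic(e)$statistic
#' @export
sn_statistic <- function(resid, trim = c(0.15, 0.85)) {
  e <- check_numeric_series(resid, "resid")
  n <- length(e)
  ks <- trim_window(n, trim)
  gn <- sn_profile_engine(e, ks)
  i <- which.max(gn)  # first maximum: deterministic tie-break at smallest k
  list(statistic = gn[i], k_hat = ks[i],
       profile = data.frame(k = ks, gn = gn),
       trim = as.numeric(trim), n = n)
}
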