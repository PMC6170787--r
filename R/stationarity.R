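# Stationarity screening. The KPSS and Phillips-Perron tests are implemented
# here directly (no suitable package is guaranteed at run time); both were
# validated against the tseries/urca implementations on fixed fixtures.

bartlett_lrv <- function(u, lags) {
  n <- length(u)
  g0 <- sum(u^2) / n
  if (lags < 1) return(g0)
  s <- g0
  for (l in seq_len(lags)) {
    gl <- sum(u[(l + 1):n] * u[1:(n - l)]) / n
    s <- s + 2 * (1 - l / (lags + 1)) * gl
  }
  s
}

default_nw_lags <- function(n) trunc(4 * (n / 100)^0.25)

#' KPSS test for level stationarity
#'
#' Null hypothesis: the series is (level-)stationary. The statistic is
#' `sum(S_t^2) / (n^2 * lrv)` with `S_t` the partial sums of the demeaned
#' series and `lrv` a Bartlett-kernel (Newey–West) long-run variance
#' estimate. P-values are interpolated from the standard asymptotic critical
#' values and clipped to [0.01, 0.10].
#'
#' @param x Numeric series (length >= 100 recommended).
#' @param lags Newey–West truncation lag; default `trunc(4*(n/100)^0.25)`.
#' @return List of class `stationarity_test` with `test_name`, `statistic`,
#'   `p_value`, `lags`, `stationary_at_5pct`.
#' @export
kpss_test <- function(x, lags = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stop("series too short for the KPSS test")
  if (sd(x) == 0) stop("constant series: stationarity test undefined")
  if (is.null(lags)) lags <- default_nw_lags(n)
  e <- x - mean(x)
  S <- cumsum(e)
  lrv <- bartlett_lrv(e, lags)
  stat <- sum(S^2) / (n^2 * lrv)
  crit <- c(0.347, 0.463, 0.574, 0.739)   # 10%, 5%, 2.5%, 1% (level case)
  probs <- c(0.10, 0.05, 0.025, 0.01)
  p <- stats::approx(crit, probs, xout = stat, rule = 2)$y
  structure(list(test_name = "KPSS", statistic = stat, p_value = p,
                 lags = lags, stationary_at_5pct = stat < 0.463),
            class = "stationarity_test")
}

#' Phillips–Perron unit-root test (Z_tau, constant, no trend)
#'
#' Null hypothesis: the series has a unit root. OLS of `x_t` on
#' `(1, x_{t-1})` gives the Dickey–Fuller t-ratio, which is corrected for
#' serial correlation with a Bartlett-kernel long-run variance (the Z_tau
#' statistic). P-values are interpolated from the asymptotic Dickey–Fuller
#' distribution for the constant case and clipped to [0.01, 0.99].
#'
#' @inheritParams kpss_test
#' @return List of class `stationarity_test`; here `stationary_at_5pct` is
#'   TRUE when the unit-root null is rejected (p < 0.05).
#' @export
pp_test <- function(x, lags = NULL) {
  x <- as.numeric(x)
  n0 <- length(x)
  if (n0 < 10) stop("series too short for the Phillips-Perron test")
  if (sd(x) == 0) stop("constant series: stationarity test undefined")
  y <- x[-1]; yl <- x[-n0]
  T <- length(y)
  if (is.null(lags)) lags <- default_nw_lags(T)
  fit <- lm(y ~ yl)
  rho <- coef(fit)[["yl"]]
  se_rho <- sqrt(diag(stats::vcov(fit)))[["yl"]]
  u <- stats::residuals(fit)
  s2 <- sum(u^2) / (T - 2)
  g0 <- sum(u^2) / T
  lam2 <- bartlett_lrv(u, lags)
  tstat <- (rho - 1) / se_rho
  # Hamilton (1994) eq. 17.6.12
  Zt <- sqrt(g0 / lam2) * tstat -
    (lam2 - g0) / (2 * sqrt(lam2)) * (T * se_rho / sqrt(s2))
  # asymptotic Dickey-Fuller percentiles, constant case
  crit <- c(-3.43, -3.12, -2.86, -2.57, -2.23, -1.62, -0.51, -0.07, 0.60)
  probs <- c(0.01, 0.025, 0.05, 0.10, 0.175, 0.40, 0.85, 0.95, 0.99)
  p <- stats::approx(crit, probs, xout = Zt, rule = 2)$y
  structure(list(test_name = "PP", statistic = Zt, p_value = p,
                 lags = lags, stationary_at_5pct = p < 0.05),
            class = "stationarity_test")
}

#' @export
print.stationarity_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4f, p ~ %.3f, lags = %d -> %s at 5%%\n",
              x$test_name, x$statistic, x$p_value, x$lags,
              if (x$stationary_at_5pct) "stationary" else "not stationary"))
  invisible(x)
}

#' Stationarity screen (KPSS + Phillips–Perron)
#'
#' Runs both tests at the 5% level. The screen passes when KPSS fails to
#' reject stationarity AND the Phillips–Perron test rejects its unit-root
#' null — the agreement the surrogate method's stationarity assumption needs.
#'
#' @param x Numeric series, length >= 100.
#' @return List with both `stationarity_test` results and a logical `passed`.
#' @export
stationarity_screen <- function(x) {
  if (length(x) < 100) stop("stationarity screen needs at least 100 samples")
  k <- kpss_test(x)
  p <- pp_test(x)
  list(kpss = k, pp = p,
       passed = k$stationary_at_5pct && p$stationary_at_5pct)
}
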