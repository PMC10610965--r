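# Normality and stationarity test battery used to justify (or rule out)
# the simple autocorrelation SNR, which assumes stationary, near-normal
# periodic signals. KS and AD come from stats/nortest; Jarque-Bera, the
# augmented Dickey-Fuller test and the Lo-MacKinlay variance-ratio test
# are implemented here (no installed package provides them).

battery_row <- function(test, statistic, p_value, critical_value, alpha,
                        reject, decision_if_reject, decision_if_not) {
  data.frame(
    test = test,
    statistic = statistic,
    p_value = p_value,
    critical_value = critical_value,
    alpha = alpha,
    reject = reject,
    decision = if (reject) decision_if_reject else decision_if_not,
    stringsAsFactors = FALSE
  )
}

#' Jarque-Bera normality test
#'
#' `JB = n/6 * (S^2 + (K - 3)^2 / 4)` from the sample skewness `S` and
#' kurtosis `K`, referred to its asymptotic chi-square distribution with
#' 2 degrees of freedom.
#'
#' @param v Numeric vector, length >= 20.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
jarque_bera <- function(v) {
  n <- length(v)
  if (n < 20) {
    stop("jarque_bera: need at least 20 observations", call. = FALSE)
  }
  z <- v - mean(v)
  m2 <- mean(z^2)
  s <- mean(z^3) / m2^1.5
  k <- mean(z^4) / m2^2
  stat <- n / 6 * (s^2 + (k - 3)^2 / 4)
  list(statistic = stat, p_value = 1 - stats::pchisq(stat, df = 2), df = 2)
}

#' Normality test battery
#'
#' Kolmogorov-Smirnov (on the standardized sample against the standard
#' normal), Anderson-Darling, and Jarque-Bera tests, one row each with
#' statistic, p-value, critical value at `alpha`, and the normal /
#' non-normal decision. Critical values: KS asymptotic
#' `1.3581 / sqrt(n)` (alpha = 0.05), AD 0.752 for the
#' estimated-parameters case, JB the chi-square(2) quantile.
#'
#' @param x A [time_series()] with at least 20 samples.
#' @param alpha Significance level (default 0.05).
#' @return Data frame of class `ridgesnr_battery` with columns `test`,
#'   `statistic`, `p_value`, `critical_value`, `alpha`, `reject`,
#'   `decision`.
#' @export
normality_battery <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "ridgesnr_ts"))
  v <- x$samples
  n <- length(v)
  if (n < 20) {
    stop("normality_battery: need at least 20 samples", call. = FALSE)
  }
  z <- (v - mean(v)) / stats::sd(v)

  ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
  # asymptotic KS critical value; the 0.05 constant is 1.3581
  ks_crit <- sqrt(-log(alpha / 2) / 2) / sqrt(n)
  ad <- nortest::ad.test(v)
  # AD critical values for unknown mean/variance (Stephens): interpolate
  ad_tab <- data.frame(
    alpha = c(0.10, 0.05, 0.025, 0.01),
    crit = c(0.631, 0.752, 0.873, 1.035)
  )
  ad_crit <- stats::approx(ad_tab$alpha, ad_tab$crit, xout = alpha,
    rule = 2)$y
  jb <- jarque_bera(v)
  jb_crit <- stats::qchisq(1 - alpha, df = 2)

  out <- rbind(
    battery_row("Kolmogorov-Smirnov", unname(ks$statistic), ks$p.value,
      ks_crit, alpha, ks$p.value < alpha, "non-normal", "normal"),
    battery_row("Anderson-Darling", unname(ad$statistic), ad$p.value,
      ad_crit, alpha, ad$p.value < alpha, "non-normal", "normal"),
    battery_row("Jarque-Bera", jb$statistic, jb$p_value,
      jb_crit, alpha, jb$p_value < alpha, "non-normal", "normal")
  )
  class(out) <- c("ridgesnr_battery", class(out))
  out
}

# Dickey-Fuller t-statistic null quantiles for the no-constant variant,
# calibrated by Monte Carlo (200k random walks of length 1000); the
# 1%/5%/90%/95% points reproduce the published Fuller table values
# (-2.56, -1.95, 0.89, 1.29).
.df_nc_probs <- c(
  0.001, 0.005, 0.01, 0.025, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5,
  0.6, 0.7, 0.8, 0.9, 0.95, 0.975, 0.99, 0.995, 0.999
)
.df_nc_quants <- c(
  -3.2677, -2.7982, -2.5632, -2.2319, -1.9469, -1.6181, -1.2345,
  -0.9611, -0.7293, -0.4957, -0.2362, 0.0555, 0.4050, 0.8932,
  1.2894, 1.6280, 2.0079, 2.2676, 2.7971
)

#' Augmented Dickey-Fuller unit-root test (no constant)
#'
#' Regresses the differenced series on its lagged level (and `lags`
#' lagged differences) without an intercept or trend term and returns the
#' t-statistic on the lagged level. The null is a unit root
#' (non-stationarity); rejection (statistic below the critical value)
#' declares the series stationary. P-values are interpolated from
#' Monte-Carlo-calibrated null quantiles and clamped to
#' `[0.001, 0.999]`.
#'
#' @param v Numeric vector, length >= 50.
#' @param lags Number of lagged differences in the regression (default 0,
#'   the plain Dickey-Fuller form).
#' @param alpha Significance level (default 0.05).
#' @return List with `statistic`, `p_value`, `critical_value`, `reject`.
#' @export
adf_test <- function(v, lags = 0L, alpha = 0.05) {
  n <- length(v)
  if (n < 50) {
    stop("adf_test: need at least 50 observations", call. = FALSE)
  }
  lags <- as.integer(lags)
  dy <- diff(v)
  ylag <- v[-n]
  if (lags > 0L) {
    nd <- length(dy)
    rows <- (lags + 1):nd
    X <- cbind(ylag[rows], vapply(
      seq_len(lags),
      function(l) dy[rows - l],
      numeric(length(rows))
    ))
    yy <- dy[rows]
  } else {
    X <- cbind(ylag)
    yy <- dy
  }
  fit <- stats::lm.fit(X, yy)
  dof <- length(yy) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / dof
  xtx_inv <- chol2inv(chol(crossprod(X)))
  stat <- fit$coefficients[1] / sqrt(sigma2 * xtx_inv[1, 1])
  p <- stats::approx(.df_nc_quants, .df_nc_probs, xout = stat, rule = 2)$y
  crit <- stats::approx(.df_nc_probs, .df_nc_quants, xout = alpha, rule = 2)$y
  list(
    statistic = unname(stat), p_value = p, critical_value = crit,
    reject = unname(stat) < crit
  )
}

#' Lo-MacKinlay variance-ratio test
#'
#' Tests the random-walk null: the variance of `q`-period differences of
#' a random walk is `q` times the one-period variance, so
#' `VR(q) = Var(x_t - x_{t-q}) / (q * Var(x_t - x_{t-1}))` should be 1.
#' The homoskedastic z-statistic
#' `z = (VR - 1) * sqrt(nq / (2(2q-1)(q-1)/(3q)))` is asymptotically
#' standard normal; `|z|` above the normal quantile rejects the random
#' walk. A stationary (mean-reverting) series gives VR < 1 and a large
#' `|z|`.
#'
#' @param v Numeric vector, length >= 50.
#' @param q Aggregation period (default 2).
#' @param alpha Significance level (default 0.05).
#' @return List with `statistic` (z), `vr`, `p_value`, `critical_value`,
#'   `reject`.
#' @export
variance_ratio_test <- function(v, q = 2L, alpha = 0.05) {
  n <- length(v)
  if (n < 50) {
    stop("variance_ratio_test: need at least 50 observations", call. = FALSE)
  }
  q <- as.integer(q)
  if (q < 2) {
    stop("variance_ratio_test: 'q' must be >= 2", call. = FALSE)
  }
  d1 <- diff(v, lag = 1)
  dq <- diff(v, lag = q)
  mu <- mean(d1)
  nq <- length(d1)
  var1 <- sum((d1 - mu)^2) / nq
  varq <- sum((dq - q * mu)^2) / (q * length(dq))
  vr <- varq / var1
  z <- (vr - 1) * sqrt(nq / (2 * (2 * q - 1) * (q - 1) / (3 * q)))
  p <- 2 * stats::pnorm(-abs(z))
  crit <- stats::qnorm(1 - alpha / 2)
  list(
    statistic = z, vr = vr, p_value = p, critical_value = crit,
    reject = abs(z) > crit
  )
}

#' Stationarity test battery
#'
#' Augmented Dickey-Fuller (no constant, no trend) and Lo-MacKinlay
#' variance-ratio tests, one row each. The ADF decision column reports
#' stationary/non-stationary (rejecting the unit-root null means
#' stationary); the variance-ratio row reports random-walk /
#' not-random-walk.
#'
#' @param x A [time_series()] with at least 50 samples.
#' @param alpha Significance level (default 0.05).
#' @param adf_lags Lagged differences in the ADF regression (default 0).
#' @param vr_lag Variance-ratio aggregation period (default 2).
#' @return Data frame of class `ridgesnr_battery`; see
#'   [normality_battery()].
#' @export
stationarity_battery <- function(x, alpha = 0.05, adf_lags = 0L, vr_lag = 2L) {
  stopifnot(inherits(x, "ridgesnr_ts"))
  v <- x$samples
  if (length(v) < 50) {
    stop("stationarity_battery: need at least 50 samples", call. = FALSE)
  }
  adf <- adf_test(v, lags = adf_lags, alpha = alpha)
  vr <- variance_ratio_test(v, q = vr_lag, alpha = alpha)
  out <- rbind(
    battery_row("Augmented Dickey-Fuller", adf$statistic, adf$p_value,
      adf$critical_value, alpha, adf$reject, "stationary", "non-stationary"),
    battery_row("Variance ratio", vr$statistic, vr$p_value,
      vr$critical_value, alpha, vr$reject, "not-random-walk", "random-walk")
  )
  class(out) <- c("ridgesnr_battery", class(out))
  out
}
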