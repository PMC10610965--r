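#' Autocorrelation-based SNR
#'
#' The quick reference estimator for periodic stationary signals: the
#' autocorrelation at lag zero divided by the mean magnitude of the
#' autocorrelation over all nonzero lags (biased sample autocorrelation of
#' the mean-removed signal). The rationale is that the autocorrelation of
#' noise is (near) zero away from lag zero, so the off-zero mean estimates
#' the noise floor. Note that the signed mean is unusable here: for any
#' mean-removed series the biased autocorrelations over nonzero lags sum
#' to exactly -1/2, so only the magnitude carries information.
#'
#' Valid only for stationary periodic signals; a persistent periodic
#' autocorrelation raises the denominator, so structured signals score
#' *lower* than white noise - one reason this estimator is unsuited to
#' non-stationary biosignals.
#'
#' @param x A [time_series()] with at least 2 samples and nonzero
#'   variance.
#' @return The SNR ratio (unitless, positive).
#' @export
autocorr_snr <- function(x) {
  stopifnot(inherits(x, "ridgesnr_ts"))
  v <- x$samples
  if (stats::var(v) == 0) {
    stop("autocorr_snr: zero-variance signal", call. = FALSE)
  }
  n <- length(v)
  r <- stats::acf(v, lag.max = n - 1, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  r0 <- r[1]
  r0 / mean(abs(r[-1]))
}

#' Maximum wavelet decomposition level
#'
#' The rule-of-thumb upper bound on the discrete wavelet decomposition
#' depth: `floor(log2(n))` for a signal of length `n`.
#'
#' @param n Signal length, >= 2.
#' @return Integer level.
#' @export
#' @examples
#' max_dwt_level(1024) # 10
max_dwt_level <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("max_dwt_level: 'n' must be a single count >= 2", call. = FALSE)
  }
  as.integer(floor(log2(n)))
}

#' MAD-based noise scale
#'
#' Robust noise standard deviation estimate from wavelet detail
#' coefficients: the median absolute deviation about the median, divided
#' by 0.6745 (the normal consistency constant), as used by the universal
#' threshold rule.
#'
#' @param coeffs Numeric vector (nonempty).
#' @return Nonnegative scalar.
#' @export
#' @examples
#' mad_sigma(1:5) # 1 / 0.6745
mad_sigma <- function(coeffs) {
  if (!length(coeffs)) {
    stop("mad_sigma: empty coefficient vector", call. = FALSE)
  }
  stats::median(abs(coeffs - stats::median(coeffs))) / 0.6745
}

# --- periodized orthogonal DWT (sym4 by default) -------------------------
#
# No installed R package provides a discrete wavelet transform, so the
# classical baseline carries its own: a circular (periodized) Mallat
# transform with orthonormal filter banks. Orthogonality gives exact
# Parseval energy conservation and perfect reconstruction, which the
# monotonicity of the classical MSE/SNR curves relies on. Filter constants
# are the published symlet/Daubechies values. Coefficient indexing follows
# the common periodization convention (verified against an independent
# implementation at build time): a_k = sum_m h_m x_{(2k - m + L/2) mod n}.

.wavelet_filters <- list(
  sym4 = list(
    dec_lo = c(
      -0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
      0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
      -0.012603967262037833, 0.0322231006040427
    ),
    dec_hi = c(
      -0.0322231006040427, -0.012603967262037833, 0.09921954357684722,
      0.29785779560527736, -0.8037387518059161, 0.49761866763201545,
      0.02963552764599851, -0.07576571478927333
    )
  ),
  db4 = list(
    dec_lo = c(
      -0.010597401784997278, 0.032883011666982945, 0.030841381835986965,
      -0.18703481171888114, -0.02798376941698385, 0.6308807679295904,
      0.7148465705525415, 0.23037781330885523
    ),
    dec_hi = c(
      -0.23037781330885523, 0.7148465705525415, -0.6308807679295904,
      -0.02798376941698385, 0.18703481171888114, 0.030841381835986965,
      -0.032883011666982945, -0.010597401784997278
    )
  )
)

dwt_index <- function(k, m, n, L) (2 * k - m + L %/% 2) %% n + 1

dwt_step <- function(x, lo, hi) {
  n <- length(x)
  L <- length(lo)
  half <- n %/% 2L
  m <- 0:(L - 1)
  a <- numeric(half)
  d <- numeric(half)
  for (k in 0:(half - 1L)) {
    idx <- dwt_index(k, m, n, L)
    a[k + 1L] <- sum(lo * x[idx])
    d[k + 1L] <- sum(hi * x[idx])
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, lo, hi) {
  half <- length(a)
  n <- 2L * half
  L <- length(lo)
  m <- 0:(L - 1)
  x <- numeric(n)
  for (k in 0:(half - 1L)) {
    idx <- dwt_index(k, m, n, L)
    x[idx] <- x[idx] + a[k + 1L] * lo + d[k + 1L] * hi
  }
  x
}

# Full decomposition of an even-dyadic-length vector. Returns approximation
# at the deepest level plus detail vectors per level (level 1 = finest).
dwt_decompose <- function(x, level, wavelet = "sym4") {
  f <- .wavelet_filters[[wavelet]]
  if (is.null(f)) {
    stop("unknown wavelet '", wavelet, "'; available: ",
      paste(names(.wavelet_filters), collapse = ", "),
      call. = FALSE
    )
  }
  details <- vector("list", level)
  a <- x
  for (lev in seq_len(level)) {
    st <- dwt_step(a, f$dec_lo, f$dec_hi)
    details[[lev]] <- st$d
    a <- st$a
  }
  list(approx = a, details = details, wavelet = wavelet, level = level)
}

dwt_reconstruct <- function(dec) {
  f <- .wavelet_filters[[dec$wavelet]]
  a <- dec$approx
  for (lev in rev(seq_len(dec$level))) {
    a <- idwt_step(a, dec$details[[lev]], f$dec_lo, f$dec_hi)
  }
  a
}

soft_threshold <- function(d, thr) sign(d) * pmax(abs(d) - thr, 0)
hard_threshold <- function(d, thr) d * (abs(d) > thr)

#' Denoise a signal by wavelet shrinkage
#'
#' Classical discrete-wavelet denoising: decompose to `level`, threshold
#' every detail level at `T = tm * sigma * sqrt(2 * log(n))` - the
#' universal rule with the noise scale `sigma` estimated by [mad_sigma()]
#' from the finest-level details, scaled by the threshold multiplier
#' `tm` - and reconstruct. Signals whose length is not divisible by
#' `2^level` are symmetrically padded to the next multiple before the
#' (periodized) transform and truncated afterwards.
#'
#' @param x A [time_series()].
#' @param tm Threshold multiplier, > 0.
#' @param wavelet `"sym4"` (default) or `"db4"`.
#' @param level Decomposition depth; defaults to
#'   `min(4, max_dwt_level(n))` and must not exceed [max_dwt_level()].
#' @param rule `"soft"` (default) or `"hard"` thresholding.
#' @return The denoised `ridgesnr_ts`.
#' @export
dwt_denoise <- function(x, tm, wavelet = "sym4", level = NULL,
                        rule = c("soft", "hard")) {
  stopifnot(inherits(x, "ridgesnr_ts"))
  rule <- match.arg(rule)
  if (!is.numeric(tm) || length(tm) != 1L || tm <= 0) {
    stop("dwt_denoise: 'tm' must be a positive scalar", call. = FALSE)
  }
  n <- length(x$samples)
  max_lev <- max_dwt_level(n)
  if (is.null(level)) level <- min(4L, max_lev)
  if (level < 1 || level > max_lev) {
    stop(sprintf(
      "dwt_denoise: 'level' must be in 1..%d for n = %d", max_lev, n
    ), call. = FALSE)
  }
  block <- 2^level
  n_pad <- ceiling(n / block) * block
  v <- x$samples
  if (n_pad > n) {
    v <- c(v, v[n - seq_len(n_pad - n) + 1])
  }
  dec <- dwt_decompose(v, level, wavelet)
  sigma <- mad_sigma(dec$details[[1]])
  thr <- tm * sigma * sqrt(2 * log(n))
  shrink <- if (rule == "soft") soft_threshold else hard_threshold
  dec$details <- lapply(dec$details, shrink, thr = thr)
  xd <- dwt_reconstruct(dec)[seq_len(n)]
  time_series(xd, x$fs, label = x$label)
}

#' Classical MSE/SNR curves over a threshold-multiplier grid
#'
#' Runs [dwt_denoise()] at every threshold multiplier in the grid and
#' records the mean-squared error between original and denoised signal and
#' the classical SNR `10 * log10(||xd||^2 / ||x - xd||^2)`. As the
#' multiplier grows, denoising becomes more aggressive, so the MSE curve
#' is non-decreasing and the SNR curve non-increasing. The breakpoint
#' multiplier is selected where the min-max normalized curves intersect
#' (see [select_tm_at_intersection()]).
#'
#' @param x A [time_series()].
#' @param tm_grid Increasing positive grid of multipliers; default 100
#'   linearly spaced values from 0.5 to 10.
#' @param wavelet,level,rule Passed to [dwt_denoise()].
#' @return An object of class `ridgesnr_classical` with fields `tm_grid`,
#'   `mse_curve`, `snr_curve` (dB), `selected_tm`, `snr_at_tm` (dB,
#'   interpolated at `selected_tm`), `wavelet`, `level`, `threshold_rule`,
#'   `denoised` (list of denoised sample vectors, one per grid point).
#' @export
classical_snr_curve <- function(x, tm_grid = seq(0.5, 10, length.out = 100),
                                wavelet = "sym4", level = NULL,
                                rule = c("soft", "hard")) {
  stopifnot(inherits(x, "ridgesnr_ts"))
  rule <- match.arg(rule)
  if (!length(tm_grid) || any(tm_grid <= 0) ||
    (length(tm_grid) > 1 && any(diff(tm_grid) <= 0))) {
    stop("classical_snr_curve: 'tm_grid' must be positive and increasing",
      call. = FALSE
    )
  }
  if (is.null(level)) level <- min(4L, max_dwt_level(length(x$samples)))
  mse <- numeric(length(tm_grid))
  snr <- numeric(length(tm_grid))
  den <- vector("list", length(tm_grid))
  for (i in seq_along(tm_grid)) {
    xd <- dwt_denoise(x, tm_grid[i], wavelet = wavelet, level = level,
      rule = rule)$samples
    resid <- x$samples - xd
    mse[i] <- mean(resid^2)
    snr[i] <- 10 * log10(sum(xd^2) / sum(resid^2))
    den[[i]] <- xd
  }
  res <- structure(
    list(
      tm_grid = tm_grid, mse_curve = mse, snr_curve = snr,
      selected_tm = NA_real_, snr_at_tm = NA_real_,
      wavelet = wavelet, level = as.integer(level), threshold_rule = rule,
      denoised = den
    ),
    class = "ridgesnr_classical"
  )
  res$selected_tm <- select_tm_at_intersection(res)
  res$snr_at_tm <- stats::approx(tm_grid, snr, xout = res$selected_tm)$y
  res
}

#' @export
print.ridgesnr_classical <- function(x, ...) {
  cat(sprintf(
    "<ridgesnr_classical> %s level %d, %s threshold: TM = %.3f, SNR = %.2f dB\n",
    x$wavelet, x$level, x$threshold_rule, x$selected_tm, x$snr_at_tm
  ))
  invisible(x)
}

#' Threshold multiplier at the MSE/SNR curve intersection
#'
#' MSE and SNR have incommensurate units, so each curve is min-max
#' normalized to \[0, 1\] first; with a non-decreasing MSE and a
#' non-increasing SNR the normalized curves cross exactly once. The
#' returned multiplier is linearly interpolated between the bracketing
#' grid points.
#'
#' @param result A `ridgesnr_classical` from [classical_snr_curve()].
#' @return The breakpoint threshold multiplier.
#' @export
select_tm_at_intersection <- function(result) {
  stopifnot(inherits(result, "ridgesnr_classical"))
  tm <- result$tm_grid
  if (length(tm) == 1L) {
    return(tm)
  }
  norm01 <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) {
      stop(
        "select_tm_at_intersection: flat curve after normalization; ",
        "no crossing exists (range of curve is zero)",
        call. = FALSE
      )
    }
    (v - rng[1]) / diff(rng)
  }
  g <- norm01(result$mse_curve) - norm01(result$snr_curve)
  i <- which(g >= 0)[1]
  if (is.na(i)) {
    stop("select_tm_at_intersection: normalized curves never cross",
      call. = FALSE
    )
  }
  if (i == 1L || g[i] == 0) {
    return(tm[i])
  }
  # linear interpolation between the bracketing grid points
  tm[i - 1] + (tm[i] - tm[i - 1]) * (0 - g[i - 1]) / (g[i] - g[i - 1])
}
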