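#' Wavelet analysis parameters
#'
#' Parameters of the continuous wavelet transform: the analytic Morlet
#' mother wavelet with central frequency `omega0` (rad), and a geometric
#' scale grid with `voices_per_octave` scales per octave spanning the
#' analysis band `[freq_min_hz, freq_max_hz]`. The defaults cover
#' 0.3-8 Hz, bracketing the 0.5-5 Hz physiological heart-rate band with
#' margin on both sides.
#'
#' @param family Mother wavelet family; only `"morlet"` (analytic Morlet)
#'   is implemented.
#' @param omega0 Central frequency of the wavelet in rad; 6 is the
#'   standard choice for ridge analysis (it makes the scale-to-frequency
#'   identity essentially exact while keeping admissibility error
#'   negligible).
#' @param voices_per_octave Scales per octave (>= 4); 16 by default.
#' @param freq_min_hz,freq_max_hz Analysis band in Hz; must satisfy
#'   `0 < freq_min_hz < freq_max_hz <= fs/2` for the signal analyzed.
#' @return An object of class `ridgesnr_wavelet_params`.
#' @export
wavelet_params <- function(family = "morlet", omega0 = 6,
                           voices_per_octave = 16,
                           freq_min_hz = 0.3, freq_max_hz = 8) {
  if (!identical(family, "morlet")) {
    stop("wavelet_params: only the analytic Morlet family is implemented",
      call. = FALSE
    )
  }
  if (!is.numeric(omega0) || length(omega0) != 1L || omega0 <= 0) {
    stop("wavelet_params: 'omega0' must be a positive scalar (rad)",
      call. = FALSE
    )
  }
  if (voices_per_octave < 4) {
    stop("wavelet_params: 'voices_per_octave' must be >= 4", call. = FALSE)
  }
  if (!(freq_min_hz > 0 && freq_min_hz < freq_max_hz)) {
    stop("wavelet_params: need 0 < freq_min_hz < freq_max_hz", call. = FALSE)
  }
  structure(
    list(
      family = family, omega0 = omega0,
      voices_per_octave = voices_per_octave,
      freq_min_hz = freq_min_hz, freq_max_hz = freq_max_hz
    ),
    class = "ridgesnr_wavelet_params"
  )
}

#' Convert a wavelet scale to frequency
#'
#' The scale-to-frequency identity `f = omega0 / (2 * pi * s)` with the
#' scale `s` in seconds. Strictly decreasing in `s`.
#'
#' @param scale Scale(s) in seconds; must be positive. Scales quoted in
#'   samples (as scalogram axes sometimes are) convert via
#'   `scale_samples / fs`.
#' @param params A [wavelet_params()] supplying `omega0`.
#' @return Frequency in Hz.
#' @export
#' @examples
#' scale_to_frequency(1, wavelet_params(omega0 = 2 * pi)) # 1 Hz
#' scale_to_frequency(51 / 64, wavelet_params(omega0 = 4.347)) # ~0.868 Hz
scale_to_frequency <- function(scale, params = wavelet_params()) {
  stopifnot(inherits(params, "ridgesnr_wavelet_params"))
  if (any(scale <= 0)) {
    stop("scale_to_frequency: scales must be positive", call. = FALSE)
  }
  params$omega0 / (2 * pi * scale)
}

#' Convert a frequency to a wavelet scale
#'
#' Inverse of [scale_to_frequency()]: `s = omega0 / (2 * pi * f)` seconds.
#'
#' @param freq_hz Frequency in Hz, positive.
#' @param params A [wavelet_params()].
#' @return Scale in seconds.
#' @export
frequency_to_scale <- function(freq_hz, params = wavelet_params()) {
  stopifnot(inherits(params, "ridgesnr_wavelet_params"))
  if (any(freq_hz <= 0)) {
    stop("frequency_to_scale: frequencies must be positive", call. = FALSE)
  }
  params$omega0 / (2 * pi * freq_hz)
}

#' Continuous wavelet transform
#'
#' FFT-based analytic-Morlet CWT with L2 (`1/sqrt(s)`) normalization.
#' Coefficients are computed on a geometric scale grid with
#' `voices_per_octave` scales per octave spanning the analysis band.
#' The signal is symmetrically padded to suppress wrap-around; a
#' cone-of-influence boundary mask is returned but not applied.
#'
#' @param x A [time_series()].
#' @param params A [wavelet_params()]; the analysis band must lie within
#'   `(0, fs/2]`.
#' @return An object of class `ridgesnr_cwt` with fields `coeffs` (complex
#'   M x N matrix, scales in rows ordered by increasing scale, i.e.
#'   decreasing frequency), `scales` (seconds), `freqs_hz`, `fs`, `coi`
#'   (logical M x N mask, `TRUE` where edge effects are significant), and
#'   `params`.
#' @export
#' @examples
#' x <- time_series(sin(2 * pi * (0:2047) / 64), fs = 64)
#' cw <- compute_cwt(x)
#' cw$freqs_hz[which.max(rowMeans(Mod(cw$coeffs)))]
compute_cwt <- function(x, params = wavelet_params()) {
  stopifnot(inherits(x, "ridgesnr_ts"), inherits(params, "ridgesnr_wavelet_params"))
  if (params$freq_max_hz > x$fs / 2 + 1e-12) {
    stop(sprintf(
      "compute_cwt: analysis band upper edge %g Hz exceeds Nyquist %g Hz",
      params$freq_max_hz, x$fs / 2
    ), call. = FALSE)
  }
  n <- length(x$samples)
  n_oct <- log2(params$freq_max_hz / params$freq_min_hz)
  k <- 0:ceiling(n_oct * params$voices_per_octave)
  freqs <- params$freq_max_hz * 2^(-k / params$voices_per_octave)
  scales <- frequency_to_scale(freqs, params) # seconds, increasing

  # symmetric padding on both sides, then FFT
  pad <- n
  left <- x$samples[pmin(pad:1, n)]
  right <- x$samples[pmax(n - (1:pad) + 1, 1)]
  xp <- c(left, x$samples, right)
  np <- length(xp)
  xf <- stats::fft(xp)
  # angular frequency grid in rad/s (wrapped)
  kk <- 0:(np - 1)
  kk[kk > np / 2] <- kk[kk > np / 2] - np
  omega <- 2 * pi * kk * x$fs / np

  coeffs <- matrix(0i, length(scales), n)
  norm_const <- pi^(-0.25)
  for (i in seq_along(scales)) {
    s <- scales[i]
    # analytic Morlet: support on positive frequencies only
    psi_hat <- numeric(np)
    pos <- omega > 0
    psi_hat[pos] <- norm_const * exp(-0.5 * (s * omega[pos] - params$omega0)^2)
    row <- stats::fft(xf * psi_hat * sqrt(s * x$fs), inverse = TRUE) / np
    coeffs[i, ] <- row[(pad + 1):(pad + n)]
  }

  # cone of influence: e-folding time of the Morlet envelope is sqrt(2)*s
  tgrid <- (seq_len(n) - 1) / x$fs
  tmax <- (n - 1) / x$fs
  coi <- matrix(FALSE, length(scales), n)
  for (i in seq_along(scales)) {
    efold <- sqrt(2) * scales[i]
    coi[i, ] <- tgrid < efold | (tmax - tgrid) < efold
  }

  structure(
    list(
      coeffs = coeffs, scales = scales, freqs_hz = freqs,
      fs = x$fs, coi = coi, params = params
    ),
    class = "ridgesnr_cwt"
  )
}

#' @export
print.ridgesnr_cwt <- function(x, ...) {
  cat(sprintf(
    "<ridgesnr_cwt> %d scales (%.3g-%.3g Hz) x %d samples @ %g Hz\n",
    length(x$scales), min(x$freqs_hz), max(x$freqs_hz),
    ncol(x$coeffs), x$fs
  ))
  invisible(x)
}

#' Energy-normalized wavelet scalogram
#'
#' The scalogram entry at scale i and time j is
#' `|W_ij|^2 / sum(|W|^2)`, the proportion of the signal's wavelet energy
#' in that time-frequency cell; the matrix sums to one.
#'
#' @param cw A `ridgesnr_cwt` from [compute_cwt()]; must contain at least
#'   one nonzero coefficient.
#' @return An object of class `ridgesnr_scalogram` with fields `ws`
#'   (nonnegative M x N matrix summing to 1), `scales`, `freqs_hz`, `fs`.
#' @export
compute_scalogram <- function(cw) {
  stopifnot(inherits(cw, "ridgesnr_cwt"))
  p2 <- Mod(cw$coeffs)^2
  tot <- sum(p2)
  if (tot == 0) {
    stop("compute_scalogram: all-zero coefficients, normalization undefined",
      call. = FALSE
    )
  }
  structure(
    list(ws = p2 / tot, scales = cw$scales, freqs_hz = cw$freqs_hz, fs = cw$fs),
    class = "ridgesnr_scalogram"
  )
}

#' @export
print.ridgesnr_scalogram <- function(x, ...) {
  cat(sprintf(
    "<ridgesnr_scalogram> %d x %d, total mass %.9f\n",
    nrow(x$ws), ncol(x$ws), sum(x$ws)
  ))
  invisible(x)
}
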