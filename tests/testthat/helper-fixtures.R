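# Shared fixtures: fake CWT objects for unit-testing ridge logic without
# running the transform, and a brute-force ridge oracle.

fake_cwt <- function(coeffs, fs = 64, freq_max = 8, voices = 16) {
  m <- nrow(coeffs)
  freqs <- freq_max * 2^(-(0:(m - 1)) / voices)
  params <- wavelet_params(
    voices_per_octave = voices,
    freq_min_hz = min(freqs) * 0.99, freq_max_hz = freq_max
  )
  structure(
    list(
      coeffs = coeffs, scales = frequency_to_scale(freqs, params),
      freqs_hz = freqs, fs = fs,
      coi = matrix(FALSE, m, ncol(coeffs)), params = params
    ),
    class = "ridgesnr_cwt"
  )
}

# Independent oracle: per-column scan for strict interior local maxima of
# |W| along the scale axis, plateau -> lowest-scale member.
ridge_oracle <- function(absW) {
  m <- nrow(absW)
  n <- ncol(absW)
  mask <- matrix(FALSE, m, n)
  for (j in seq_len(n)) {
    k <- 1L
    while (k <= m) {
      e <- k
      while (e < m && absW[e + 1L, j] == absW[k, j]) e <- e + 1L
      if (k > 1L && e < m &&
        absW[k - 1L, j] < absW[k, j] && absW[e + 1L, j] < absW[k, j]) {
        mask[k, j] <- TRUE
      }
      k <- e + 1L
    }
  }
  mask
}

sine_ts <- function(freq_hz, duration_s = 32, fs = 64, amp = 1) {
  t <- (0:(duration_s * fs - 1)) / fs
  time_series(amp * sin(2 * pi * freq_hz * t), fs = fs)
}
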