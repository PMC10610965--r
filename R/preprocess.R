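#' Band-pass filter specification
#'
#' Design constraints for the IIR band-pass applied before wavelet
#' analysis. The defaults bracket the physiological heart-rate band
#' (30-300 beats per minute): first stop-band edge 0.1 Hz with 40 dB
#' attenuation, pass-band 0.5-5 Hz with 1 dB ripple, second stop-band
#' edge 6 Hz with 50 dB attenuation, at a 64 Hz sampling rate, elliptic
#' design.
#'
#' @param stop1_hz,pass1_hz,pass2_hz,stop2_hz Band edges in Hz; must
#'   satisfy `0 < stop1 < pass1 < pass2 < stop2 < fs/2`.
#' @param astop1_db Minimum attenuation in the first stop-band, dB.
#' @param apass_db Maximum pass-band ripple, dB.
#' @param astop2_db Minimum attenuation in the second stop-band, dB.
#' @param fs Sampling rate in Hz.
#' @param method Design method; only `"elliptic"` is implemented.
#' @return An object of class `ridgesnr_bandpass_spec`.
#' @export
bandpass_spec <- function(stop1_hz = 0.1, pass1_hz = 0.5,
                          pass2_hz = 5, stop2_hz = 6,
                          astop1_db = 40, apass_db = 1, astop2_db = 50,
                          fs = 64, method = "elliptic") {
  if (!identical(method, "elliptic")) {
    stop("bandpass_spec: only the elliptic design method is implemented",
      call. = FALSE
    )
  }
  edges <- c(stop1_hz, pass1_hz, pass2_hz, stop2_hz)
  if (!all(is.finite(edges)) || any(edges <= 0) ||
    any(diff(edges) <= 0) || stop2_hz >= fs / 2) {
    stop(
      "bandpass_spec: band edges must satisfy ",
      "0 < stop1_hz < pass1_hz < pass2_hz < stop2_hz < fs/2",
      call. = FALSE
    )
  }
  if (astop1_db <= 0 || apass_db <= 0 || astop2_db <= 0) {
    stop("bandpass_spec: attenuations and ripple must be positive (dB)",
      call. = FALSE
    )
  }
  structure(
    list(
      stop1_hz = stop1_hz, pass1_hz = pass1_hz, pass2_hz = pass2_hz,
      stop2_hz = stop2_hz, astop1_db = astop1_db, apass_db = apass_db,
      astop2_db = astop2_db, fs = fs, method = method
    ),
    class = "ridgesnr_bandpass_spec"
  )
}

# Pair conjugate roots into 2x real polynomials. Roots are sorted by
# distance from the unit circle so that high-Q sections come last in the
# cascade (standard ordering for numerical headroom).
pair_conjugates <- function(r) {
  used <- logical(length(r))
  pairs <- list()
  ord <- order(abs(abs(r) - 1), decreasing = TRUE)
  for (i in ord) {
    if (used[i]) next
    used[i] <- TRUE
    if (abs(Im(r[i])) < 1e-10) {
      # real root: pair with the nearest unused real root, or alone
      j <- which(!used & abs(Im(r)) < 1e-10)
      if (length(j)) {
        j <- j[which.min(abs(Re(r[j]) - Re(r[i])))]
        used[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(Re(r[i]), Re(r[j]))
      } else {
        pairs[[length(pairs) + 1L]] <- Re(r[i])
      }
    } else {
      j <- which(!used)
      j <- j[which.min(Mod(r[j] - Conj(r[i])))]
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- r[c(i, j)]
    }
  }
  pairs
}

poly_from_roots <- function(r) {
  p <- 1
  for (root in r) p <- c(p, 0) - c(0, p * root)
  Re(p)
}

# zpk -> second-order sections. Each pole pair is matched with the zero
# pair closest to it in the z-plane; overall gain is applied to the first
# section.
zpk_to_sos <- function(zero, pole, gain) {
  pp <- pair_conjugates(pole)
  zp <- pair_conjugates(zero)
  nsec <- max(length(pp), length(zp))
  sos <- matrix(0, nsec, 6)
  zused <- logical(length(zp))
  for (k in seq_along(pp)) {
    a <- poly_from_roots(pp[[k]])
    # nearest unused zero pair
    cand <- which(!zused)
    if (length(cand)) {
      d <- vapply(cand, function(i) min(Mod(zp[[i]][1] - pp[[k]]))
      , numeric(1))
      pick <- cand[which.min(d)]
      zused[pick] <- TRUE
      b <- poly_from_roots(zp[[pick]])
    } else {
      b <- 1
    }
    sos[k, ] <- c(b, rep(0, 3 - length(b)), a, rep(0, 3 - length(a)))
  }
  # leftover zero pairs (more zeros than poles shouldn't happen for these
  # designs, but keep it total)
  for (i in which(!zused)) {
    b <- poly_from_roots(zp[[i]])
    sos <- rbind(sos, c(b, rep(0, 3 - length(b)), 1, 0, 0))
  }
  sos[1, 1:3] <- sos[1, 1:3] * gain
  sos
}

#' Design the pre-analysis elliptic band-pass filter
#'
#' Finds the minimum-order elliptic band-pass meeting the specification
#' and returns it as a cascade of second-order sections (biquads). The
#' design runs through the analog elliptic prototype with a band transform
#' and bilinear mapping, keeping zeros and poles symbolic until the final
#' biquad pairing: at a 0.5 Hz pass-band edge on a 64 Hz rate the expanded
#' transfer-function polynomial is numerically unstable, while the cascade
#' is not.
#'
#' @param spec A [bandpass_spec()].
#' @return An object of class `ridgesnr_sos_filter` with fields `sos`
#'   (n x 6 matrix, columns b0 b1 b2 a0 a1 a2), `order` (analog prototype
#'   order), `spec`, `zero`, `pole`, `gain`.
#' @export
#' @examples
#' f <- design_bandpass(bandpass_spec())
#' resp <- filter_response(f, freq_hz = c(0.1, 1, 6))
#' round(20 * log10(resp$magnitude), 1)
design_bandpass <- function(spec = bandpass_spec()) {
  stopifnot(inherits(spec, "ridgesnr_bandpass_spec"))
  nyq <- spec$fs / 2
  wp <- c(spec$pass1_hz, spec$pass2_hz) / nyq
  ws <- c(spec$stop1_hz, spec$stop2_hz) / nyq
  rs <- max(spec$astop1_db, spec$astop2_db)
  ord <- tryCatch(
    signal::ellipord(Wp = wp, Ws = ws, Rp = spec$apass_db, Rs = rs),
    error = function(e) {
      stop("design_bandpass: design failure: ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  # analog elliptic low-pass prototype (zeros/poles/gain), band transform,
  # bilinear map -- same path signal::ellip takes before it expands to a
  # transfer function, which we avoid.
  ncauer <- utils::getFromNamespace("ncauer", "signal")
  Tbil <- 2
  w_warp <- 2 / Tbil * tan(pi * wp / Tbil)
  zpg <- ncauer(spec$apass_db, rs, ord$n)
  zpg <- signal::sftrans(zpg, W = w_warp, stop = FALSE)
  zpg <- signal::bilinear(zpg, T = Tbil)
  if (max(abs(zpg$pole)) >= 1) {
    stop("design_bandpass: design failure: unstable pole after bilinear map",
      call. = FALSE
    )
  }
  structure(
    list(
      sos = zpk_to_sos(zpg$zero, zpg$pole, zpg$gain),
      order = ord$n, spec = spec,
      zero = zpg$zero, pole = zpg$pole, gain = zpg$gain
    ),
    class = "ridgesnr_sos_filter"
  )
}

#' @export
print.ridgesnr_sos_filter <- function(x, ...) {
  cat(sprintf(
    "<ridgesnr_sos_filter> elliptic band-pass, prototype order %d, %d biquads, fs = %g Hz\n",
    x$order, nrow(x$sos), x$spec$fs
  ))
  invisible(x)
}

#' Frequency response of a designed filter
#'
#' Evaluates the cascade magnitude/phase response at the requested
#' frequencies from the stored zeros, poles, and gain.
#'
#' @param filt A `ridgesnr_sos_filter` from [design_bandpass()].
#' @param freq_hz Frequencies at which to evaluate, Hz.
#' @return Data frame with columns `freq_hz`, `magnitude`, `phase_rad`.
#' @export
filter_response <- function(filt, freq_hz) {
  stopifnot(inherits(filt, "ridgesnr_sos_filter"))
  z <- exp(2i * pi * freq_hz / filt$spec$fs)
  h <- vapply(z, function(zi) {
    num <- prod(zi - filt$zero)
    den <- prod(zi - filt$pole)
    filt$gain * num / den
  }, complex(1))
  data.frame(freq_hz = freq_hz, magnitude = Mod(h), phase_rad = Arg(h))
}

#' Apply a designed filter to a signal
#'
#' Runs the biquad cascade over the signal. The default is a single causal
#' pass, the mode a wearable's real-time path would use; `zero_phase = TRUE`
#' applies forward-backward filtering (doubling the attenuation and
#' cancelling phase) for offline analysis.
#'
#' @param x A [time_series()]; its `fs` must match the design rate.
#' @param filt A `ridgesnr_sos_filter`.
#' @param zero_phase Logical; forward-backward filtering if `TRUE`.
#' @return A filtered `ridgesnr_ts` of the same length and rate.
#' @export
apply_filter <- function(x, filt, zero_phase = FALSE) {
  stopifnot(inherits(x, "ridgesnr_ts"), inherits(filt, "ridgesnr_sos_filter"))
  if (abs(x$fs - filt$spec$fs) > 1e-9) {
    stop(sprintf(
      "apply_filter: signal rate %g Hz does not match filter design rate %g Hz",
      x$fs, filt$spec$fs
    ), call. = FALSE)
  }
  y <- sos_filter_pass(filt$sos, x$samples)
  if (zero_phase) {
    y <- rev(sos_filter_pass(filt$sos, rev(y)))
  }
  time_series(y, x$fs, label = x$label)
}

sos_filter_pass <- function(sos, x) {
  for (k in seq_len(nrow(sos))) {
    b <- sos[k, 1:3]
    a <- sos[k, 4:6]
    x <- as.numeric(signal::filter(b, a, x))
  }
  x
}

#' Normalize a signal to the range \[-1, 1\]
#'
#' Affine min-max map so that the minimum becomes -1 and the maximum +1,
#' matching how filtered signals are displayed and compared.
#'
#' @param x A [time_series()]; must not be constant.
#' @return The normalized `ridgesnr_ts`.
#' @export
#' @examples
#' normalize_unit_range(time_series(c(0, 5, 10), fs = 1))$samples
normalize_unit_range <- function(x) {
  stopifnot(inherits(x, "ridgesnr_ts"))
  rng <- range(x$samples)
  if (diff(rng) == 0) {
    stop("normalize_unit_range: constant signal has zero range", call. = FALSE)
  }
  time_series(2 * (x$samples - rng[1]) / diff(rng) - 1, x$fs, label = x$label)
}
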