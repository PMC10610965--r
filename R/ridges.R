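#' Locate wavelet ridge points
#'
#' A ridge point is a time-frequency cell where the modulus of the wavelet
#' coefficients has a local maximum along the scale axis: the first
#' derivative of `|W|` with respect to scale vanishes and the second is
#' negative. On the discrete scale grid this is realized as a strict local
#' maximum per time column; a plateau of tied values flanked by smaller
#' ones contributes one ridge point at its lowest-scale member. The first
#' and last scale rows can never be ridge points (the derivative is
#' undefined at the grid edges).
#'
#' @param cw A `ridgesnr_cwt` with at least 3 scales.
#' @return An object of class `ridgesnr_ridge_mask` with fields `mask`
#'   (logical M x N), `d1`, `d2` (M x N central-difference first and second
#'   derivatives of `|W|` with respect to scale; `NA` on edge rows).
#' @export
find_ridge_points <- function(cw) {
  stopifnot(inherits(cw, "ridgesnr_cwt"))
  a <- Mod(cw$coeffs)
  m <- nrow(a)
  n <- ncol(a)
  if (m < 3L) {
    stop("find_ridge_points: need at least 3 scales", call. = FALSE)
  }
  s <- cw$scales
  # nonuniform central differences along the (geometric) scale grid
  h1 <- s[2:(m - 1)] - s[1:(m - 2)] # back step
  h2 <- s[3:m] - s[2:(m - 1)] # forward step
  am <- a[1:(m - 2), , drop = FALSE]
  a0 <- a[2:(m - 1), , drop = FALSE]
  ap <- a[3:m, , drop = FALSE]
  d1 <- (ap - am) / (h1 + h2)
  d2 <- 2 * (h1 * ap + h2 * am - (h1 + h2) * a0) / (h1 * h2 * (h1 + h2))

  interior <- a0 > am & a0 > ap
  ties <- a0 == ap | a0 == am
  if (any(ties)) {
    # exact ties: rescan affected columns run-by-run; a plateau flanked by
    # smaller values on both sides yields one ridge point at its
    # lowest-scale member
    for (j in which(colSums(ties) > 0)) {
      col <- a[, j]
      v <- logical(m)
      k <- 1L
      while (k <= m) {
        e <- k
        while (e < m && col[e + 1L] == col[k]) e <- e + 1L
        if (k > 1L && e < m && col[k - 1L] < col[k] && col[e + 1L] < col[k]) {
          v[k] <- TRUE
        }
        k <- e + 1L
      }
      interior[, j] <- v[2:(m - 1)]
    }
  }

  mask <- rbind(FALSE, interior, matrix(FALSE, 1, n))
  d1f <- rbind(NA_real_, d1, matrix(NA_real_, 1, n))
  d2f <- rbind(NA_real_, d2, matrix(NA_real_, 1, n))
  structure(
    list(mask = mask, d1 = d1f, d2 = d2f),
    class = "ridgesnr_ridge_mask"
  )
}

#' Assemble per-scale ridges with duration and energy statistics
#'
#' Groups ridge points by scale row. For each scale holding at least one
#' ridge point the ridge's normalized duration `bn` is the number of ridge
#' samples over the signal length; its energy is the sum of coefficient
#' magnitudes `|W|` over the ridge points (set `energy_power = 2` to use
#' squared magnitudes instead); the normalized energy `en` is that energy
#' as a percentage of the total over the whole coefficient grid; and the
#' weighted ridge energy is `ew = en * bn`, rewarding components that are
#' both intense and persistent - the defining property of the heartbeat
#' ridge.
#'
#' @param rmask A `ridgesnr_ridge_mask` from [find_ridge_points()].
#' @param cw The `ridgesnr_cwt` the mask was computed from.
#' @param energy_power 1 (default, sums `|W|`) or 2 (sums `|W|^2`).
#' @return An object of class `ridgesnr_ridge_set`: a list with `ridges`
#'   (data frame with columns `scale_index`, `scale`, `freq_hz`,
#'   `duration_samples`, `bn`, `energy`, `en`, `ew`, ordered by scale
#'   index), `signal_length`, `total_energy`, `energy_power`. Empty mask
#'   gives an empty ridge table, not an error.
#' @export
assemble_ridges <- function(rmask, cw, energy_power = 1) {
  stopifnot(
    inherits(rmask, "ridgesnr_ridge_mask"),
    inherits(cw, "ridgesnr_cwt")
  )
  if (!all(dim(rmask$mask) == dim(cw$coeffs))) {
    stop("assemble_ridges: mask shape does not match coefficient matrix",
      call. = FALSE
    )
  }
  if (!energy_power %in% c(1, 2)) {
    stop("assemble_ridges: 'energy_power' must be 1 or 2", call. = FALSE)
  }
  a <- Mod(cw$coeffs)^energy_power
  n <- ncol(a)
  total <- sum(a)
  counts <- rowSums(rmask$mask)
  keep <- which(counts > 0L)
  if (length(keep)) {
    energy <- vapply(
      keep,
      function(k) sum(a[k, rmask$mask[k, ]]),
      numeric(1)
    )
    bn <- counts[keep] / n
    en <- 100 * energy / total
    ridges <- data.frame(
      scale_index = keep,
      scale = cw$scales[keep],
      freq_hz = cw$freqs_hz[keep],
      duration_samples = counts[keep],
      bn = bn,
      energy = energy,
      en = en,
      ew = en * bn
    )
  } else {
    ridges <- data.frame(
      scale_index = integer(0), scale = numeric(0), freq_hz = numeric(0),
      duration_samples = integer(0), bn = numeric(0), energy = numeric(0),
      en = numeric(0), ew = numeric(0)
    )
  }
  structure(
    list(
      ridges = ridges, signal_length = n, total_energy = total,
      energy_power = energy_power
    ),
    class = "ridgesnr_ridge_set"
  )
}

#' @export
print.ridgesnr_ridge_set <- function(x, ...) {
  cat(sprintf(
    "<ridgesnr_ridge_set> %d ridges over %d samples\n",
    nrow(x$ridges), x$signal_length
  ))
  if (nrow(x$ridges)) {
    top <- x$ridges[which.max(x$ridges$ew), ]
    cat(sprintf(
      "  dominant: %.3f Hz (bn = %.2f, en = %.2f%%, ew = %.2f)\n",
      top$freq_hz, top$bn, top$en, top$ew
    ))
  }
  invisible(x)
}

#' Weighted ridge-energy profile
#'
#' The sequence of weighted ridge energies `ew` ordered by scale index,
#' the input to the adaptive SNR computation. Scales with no ridge point
#' contribute no entry.
#'
#' @param rset A `ridgesnr_ridge_set` from [assemble_ridges()]; must be
#'   nonempty.
#' @return Numeric vector of `ew` values with the matching frequencies
#'   (Hz) in attribute `"freq_hz"` and scale indices in `"scale_index"`.
#' @export
weighted_energy_profile <- function(rset) {
  stopifnot(inherits(rset, "ridgesnr_ridge_set"))
  if (!nrow(rset$ridges)) {
    stop("weighted_energy_profile: no ridges identified", call. = FALSE)
  }
  structure(
    rset$ridges$ew,
    freq_hz = rset$ridges$freq_hz,
    scale_index = rset$ridges$scale_index
  )
}
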