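#' Uniformly sampled time series
#'
#' The common currency between all pipeline stages: a real-valued vector of
#' samples taken at a fixed sampling rate. Bioimpedance signals are in ohms,
#' PPG signals in arbitrary units; the pipeline is unit-agnostic.
#'
#' @param samples Numeric vector of at least two finite values.
#' @param fs Sampling rate in Hz (positive scalar). Wearable bioimpedance
#'   front-ends in this application sample at 32 or 64 Hz, but any positive
#'   rate is accepted.
#' @param label Optional character label carried through reports.
#'
#' @return An object of class `ridgesnr_ts` with fields `samples`, `fs`,
#'   `label`.
#' @export
#' @examples
#' x <- time_series(sin(2 * pi * (0:639) / 64), fs = 64, label = "1 Hz tone")
#' print(x)
time_series <- function(samples, fs, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("time_series: 'samples' must contain at least 2 values", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("time_series: 'samples' must all be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("time_series: 'fs' must be a positive finite scalar (Hz)", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), label = as.character(label)),
    class = "ridgesnr_ts"
  )
}

#' @export
print.ridgesnr_ts <- function(x, ...) {
  cat(sprintf(
    "<ridgesnr_ts> %s: %d samples @ %g Hz (%.1f s)\n",
    if (nzchar(x$label)) x$label else "unlabelled",
    length(x$samples), x$fs, length(x$samples) / x$fs
  ))
  invisible(x)
}

#' @export
length.ridgesnr_ts <- function(x) length(x$samples)

#' Time axis of a time series
#'
#' @param x A `ridgesnr_ts`.
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
ts_time <- function(x) {
  stopifnot(inherits(x, "ridgesnr_ts"))
  (seq_along(x$samples) - 1) / x$fs
}

#' Read a signal from CSV
#'
#' Expects a header with columns `time_s,value`. The sampling rate is taken
#' from the time column (median spacing) unless `fs` is given; the time
#' column must be uniform to within 1% of the sample period.
#'
#' @param path CSV file path.
#' @param fs Optional sampling rate in Hz overriding the time column.
#' @param label Label attached to the returned series (defaults to the file
#'   name).
#' @return A [time_series()].
#' @export
read_signal_csv <- function(path, fs = NULL, label = basename(path)) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d))) {
    stop("read_signal_csv: CSV must have columns 'time_s' and 'value': ", path,
      call. = FALSE
    )
  }
  if (is.null(fs)) {
    dt <- diff(d$time_s)
    if (length(dt) < 1L || any(dt <= 0)) {
      stop("read_signal_csv: non-increasing time column in ", path, call. = FALSE)
    }
    period <- stats::median(dt)
    if (max(abs(dt - period)) > 0.01 * period) {
      stop("read_signal_csv: time column is not uniformly sampled in ", path,
        call. = FALSE
      )
    }
    fs <- 1 / period
  }
  time_series(d$value, fs = fs, label = label)
}

#' Write a signal to CSV
#'
#' Writes columns `time_s,value` with a header, the same layout
#' [read_signal_csv()] expects.
#'
#' @param x A `ridgesnr_ts`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path) {
  stopifnot(inherits(x, "ridgesnr_ts"))
  utils::write.csv(
    data.frame(time_s = ts_time(x), value = x$samples),
    path,
    row.names = FALSE
  )
  invisible(path)
}
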