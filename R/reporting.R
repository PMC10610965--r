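#' t-based confidence interval of a set of SNR values
#'
#' Half-width `t_{1-alpha, n-1} * s / sqrt(n)` with `s` the sample
#' standard deviation, following the convention used for the per-group
#' SNR error bars (note the one-sided `1 - alpha` quantile, as printed in
#' the field's reports, rather than `1 - alpha/2`).
#'
#' @param values Numeric vector, length >= 2.
#' @param alpha Significance level (default 0.05).
#' @return List with `mean` and `ci_halfwidth`.
#' @export
#' @examples
#' confidence_interval(c(19.2, 21.5, 23.8, 20.1))
confidence_interval <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 2) {
    stop("confidence_interval: need at least 2 values", call. = FALSE)
  }
  s <- stats::sd(values)
  tq <- stats::qt(1 - alpha, df = n - 1)
  list(mean = mean(values), ci_halfwidth = tq * s / sqrt(n))
}

#' Per-ridge report table
#'
#' The machine-readable twin of the ridge bar plots: one row per ridge
#' with its scale, frequency, normalized duration, normalized energy, and
#' weighted energy. Written as CSV when `path` is given.
#'
#' @param rset A `ridgesnr_ridge_set` from [assemble_ridges()].
#' @param path Optional CSV output path.
#' @return The ridge data frame, invisibly when written to file.
#' @export
ridge_table <- function(rset, path = NULL) {
  stopifnot(inherits(rset, "ridgesnr_ridge_set"))
  tab <- rset$ridges[, c("scale", "freq_hz", "bn", "en", "ew")]
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' JSON-serializable view of an SNR report
#'
#' @param report A `ridgesnr_snr_report` from [estimate_snr()].
#' @return A plain list: `snr_db`, `window`, `noise`, `n_ridges`,
#'   `dominant_ridge` (freq_hz, bn, en, ew), `degenerate`. Infinite SNR is
#'   encoded as the string `"Inf"`.
#' @export
snr_report_payload <- function(report) {
  stopifnot(inherits(report, "ridgesnr_snr_report"))
  dom <- report$dominant_ridge
  list(
    snr_db = if (is.finite(report$snr_db)) report$snr_db else "Inf",
    window = report$window,
    noise = report$noise,
    n_ridges = report$n_ridges %||% length(report$ew),
    dominant_ridge = if (!is.null(dom)) {
      list(freq_hz = dom$freq_hz, bn = dom$bn, en = dom$en, ew = dom$ew)
    },
    degenerate = report$degenerate
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Batch SNR estimation with per-group summaries
#'
#' Runs [estimate_snr()] over named groups of signals (e.g. one group per
#' couplant or recording condition) and summarizes each group by mean SNR,
#' standard deviation, and t-based confidence interval. Inputs can be CSV
#' file paths or `ridgesnr_ts` objects. Unreadable inputs are recorded as
#' per-file errors and skipped; the batch fails only if every input of
#' every group fails.
#'
#' @param groups Named list; each element is a list/vector of CSV paths or
#'   `ridgesnr_ts` objects.
#' @param config A [snr_config()].
#' @param alpha Significance level for the confidence intervals.
#' @param fs Sampling rate override passed to [read_signal_csv()].
#' @return An object of class `ridgesnr_batch`: data frame `summary`
#'   (group, n, mean_snr_db, sd_snr_db, ci_halfwidth - `NA` and flagged
#'   when n = 1), list `reports` (per group, per signal), list `errors`.
#' @export
run_batch <- function(groups, config = snr_config(), alpha = 0.05, fs = NULL) {
  if (!length(groups) || is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("run_batch: 'groups' must be a nonempty named list", call. = FALSE)
  }
  reports <- list()
  errors <- list()
  rows <- list()
  for (g in names(groups)) {
    inputs <- groups[[g]]
    if (!length(inputs)) {
      stop("run_batch: group '", g, "' has no inputs", call. = FALSE)
    }
    snrs <- numeric(0)
    greps <- list()
    for (i in seq_along(inputs)) {
      item <- if (is.list(inputs) && !inherits(inputs, "ridgesnr_ts")) {
        inputs[[i]]
      } else {
        inputs[i]
      }
      res <- tryCatch(
        {
          sig <- if (inherits(item, "ridgesnr_ts")) {
            item
          } else {
            read_signal_csv(as.character(item), fs = fs)
          }
          estimate_snr(sig, config)
        },
        error = function(e) e
      )
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <- list(
          group = g, index = i, message = conditionMessage(res)
        )
      } else {
        snrs <- c(snrs, res$snr_db)
        greps[[length(greps) + 1L]] <- res
      }
    }
    reports[[g]] <- greps
    if (length(snrs)) {
      ci <- if (length(snrs) >= 2) {
        confidence_interval(snrs, alpha)$ci_halfwidth
      } else {
        NA_real_
      }
      rows[[g]] <- data.frame(
        group = g, n = length(snrs), mean_snr_db = mean(snrs),
        sd_snr_db = if (length(snrs) >= 2) stats::sd(snrs) else NA_real_,
        ci_halfwidth = ci, ci_defined = length(snrs) >= 2,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    stop("run_batch: every input in every group failed", call. = FALSE)
  }
  structure(
    list(
      summary = do.call(rbind, unname(rows)),
      reports = reports, errors = errors, alpha = alpha
    ),
    class = "ridgesnr_batch"
  )
}

#' @export
print.ridgesnr_batch <- function(x, ...) {
  cat("<ridgesnr_batch>\n")
  print(x$summary, row.names = FALSE)
  if (length(x$errors)) {
    cat(sprintf("  %d input(s) failed\n", length(x$errors)))
  }
  invisible(x)
}

#' Write a batch summary to CSV and JSON
#'
#' @param batch A `ridgesnr_batch` from [run_batch()].
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @return The batch, invisibly.
#' @export
write_batch_summary <- function(batch, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(batch, "ridgesnr_batch"))
  if (!is.null(csv_path)) {
    utils::write.csv(batch$summary, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    payload <- list(
      summary = batch$summary,
      alpha = batch$alpha,
      errors = batch$errors,
      reports = lapply(batch$reports, function(g) {
        lapply(g, snr_report_payload)
      })
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(batch)
}
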