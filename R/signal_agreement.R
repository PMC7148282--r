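#' Lagged cross-correlation between paired signals
#'
#' Pearson correlation between `x[t]` and `y[t + k]` for integer lags
#' `k in [-max_lag, max_lag]`, computed over the overlapping non-missing
#' samples at each lag. The physiological rationale for the default window
#' (sympathetic conduction from wrist to fingertip) gives a delay well under
#' half a second, so 8 lags at 16 Hz is a safe window. The best lag is the
#' argmax of r, ties broken toward the smallest `|lag|`, then negative.
#'
#' @param x,y detrended, normalized [phys_ts()] with equal `fs` and aligned
#'   span (see [detrend_linear()], [znormalize()]).
#' @param max_lag maximum lag in samples (default 8).
#' @param min_overlap minimum overlapping complete pairs per lag; lags with
#'   fewer are reported as `NA`.
#' @return list of class `crosscorr_result`: `participant_id` (filled by
#'   callers), `lags`, `r_by_lag`, `best_lag`, `best_r`.
#' @export
cross_correlation_lags <- function(x, y, max_lag = 8, min_overlap = 10) {
  stop_if_not_ts(x); stop_if_not_ts(y)
  if (abs(x$fs - y$fs) > 1e-9) stop("x and y must share a sampling rate")
  vx <- x$values; vy <- y$values
  n <- min(length(vx), length(vy))
  vx <- vx[seq_len(n)]; vy <- vy[seq_len(n)]
  lags <- seq.int(-max_lag, max_lag)
  r <- rep(NA_real_, length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    if (k >= 0) {
      a <- vx[seq_len(n - k)]
      b <- vy[seq_len(n - k) + k]
    } else {
      a <- vx[seq_len(n + k) - k]
      b <- vy[seq_len(n + k)]
    }
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < min_overlap) next
    if (sd(a[ok]) == 0 || sd(b[ok]) == 0) next
    r[i] <- cor(a[ok], b[ok])
  }
  if (all(is.na(r))) stop("cross-correlation unavailable at every lag")
  # argmax with ties toward smallest |lag|, then negative lag
  best <- max(r, na.rm = TRUE)
  cand <- which(!is.na(r) & abs(r - best) < 1e-12)
  cand <- cand[order(abs(lags[cand]), lags[cand])]
  best_i <- cand[1]
  structure(list(participant_id = NA_character_, lags = lags, r_by_lag = r,
                 best_lag = lags[best_i], best_r = r[best_i]),
            class = "crosscorr_result")
}

#' Convert a lag count to seconds
#'
#' At 16 Hz a lag of 16 is one second and a lag of 8 is 0.5 s; at 4 Hz one
#' lag is 0.25 s.
#' @param lag integer lag (samples).
#' @param fs sampling rate in Hz.
#' @return duration in seconds, `lag / fs`.
#' @export
lag_duration <- function(lag, fs) {
  if (any(fs <= 0)) stop("fs must be positive")
  lag / fs
}

#' Cohort-level signal verdict
#'
#' The wearable passes the signal level only when every participant's best
#' cross-correlation exceeds the threshold (default .80, a "very high"
#' correlation). A systematic lag is reported when more than half of the
#' participants share the same best lag (sign and value); otherwise none.
#'
#' @param results list of [cross_correlation_lags()] results.
#' @param threshold correlation threshold (default 0.80).
#' @return list of class `signal_verdict`: `per_participant`, `threshold`,
#'   `systematic_lag` (integer or `NULL`), `pass`.
#' @export
cohort_signal_decision <- function(results, threshold = 0.80) {
  if (length(results) < 1) stop("need at least one participant")
  best_r <- vapply(results, function(r) r$best_r, numeric(1))
  best_lag <- vapply(results, function(r) r$best_lag, numeric(1))
  tab <- table(best_lag)
  systematic <- NULL
  if (max(tab) > length(results) / 2) {
    systematic <- as.integer(names(tab)[which.max(tab)])
  }
  structure(list(per_participant = results, threshold = threshold,
                 best_r = best_r, best_lag = best_lag,
                 systematic_lag = systematic,
                 pass = all(best_r > threshold)),
            class = "signal_verdict")
}

#' @export
print.signal_verdict <- function(x, ...) {
  cat(sprintf("<signal_verdict> %s: %d participants, best r in [%.2f, %.2f], threshold %.2f\n",
              if (x$pass) "PASS" else "FAIL", length(x$best_r),
              min(x$best_r), max(x$best_r), x$threshold))
  if (!is.null(x$systematic_lag)) {
    cat(sprintf("  systematic lag: %+d samples\n", x$systematic_lag))
  } else cat("  no systematic lag\n")
  invisible(x)
}

#' Mean-bias and variance adjustment after a signal-level pass
#'
#' When the cohort passes the correlation threshold, a residual mean
#' difference between the signals is a simple bias that can be removed by
#' centering, and a systematic variance difference by rescaling. Refused
#' when invoked without a passing signal verdict, because with low
#' correlation the source of disagreement cannot be attributed.
#'
#' @param x,y paired [phys_ts()] (reference, wearable).
#' @param verdict a passing [cohort_signal_decision()] result.
#' @return list: `bias` (mean of `y - x`), `bias_ci`, `variance_ratio`
#'   (var y / var x), `variance_ratio_ci`, and `adjusted` (`y` recentred and
#'   rescaled to `x`'s mean and variance).
#' @export
mean_bias_adjust <- function(x, y, verdict) {
  if (!inherits(verdict, "signal_verdict") || !isTRUE(verdict$pass)) {
    stop("mean_bias_adjust requires a passing signal-level verdict")
  }
  stop_if_not_ts(x); stop_if_not_ts(y)
  n <- min(length(x$values), length(y$values))
  vx <- x$values[seq_len(n)]; vy <- y$values[seq_len(n)]
  ok <- !is.na(vx) & !is.na(vy)
  d <- vy[ok] - vx[ok]
  bias_ci <- tryCatch(unname(t.test(d)$conf.int),
                      error = function(e) rep(mean(d), 2))
  vt <- var.test(vy[ok], vx[ok])
  adj <- (y$values - mean(vy[ok])) * sd(vx[ok]) / sd(vy[ok]) + mean(vx[ok])
  list(bias = mean(d), bias_ci = bias_ci,
       variance_ratio = unname(vt$estimate),
       variance_ratio_ci = unname(vt$conf.int),
       adjusted = phys_ts(adj, fs = y$fs, start_time = y$start_time,
                          units = x$units, channel = y$channel))
}
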