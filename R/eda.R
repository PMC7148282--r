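#' Smooth an EDA signal
#'
#' Zero-phase low-pass smoothing of a skin-conductance series prior to
#' trough-to-peak scoring. The default is a 2nd-order Butterworth at 1 Hz
#' run forwards and backwards (no phase shift, DC preserved); the cutoff is
#' configurable because scoring programs differ in their smoothing defaults.
#' Missing samples stay missing; each contiguous non-missing run is filtered
#' separately.
#'
#' @param x a [phys_ts()] with `channel == "eda"`.
#' @param cutoff low-pass cutoff in Hz (default 1).
#' @return a smoothed `phys_ts`.
#' @export
smooth_eda <- function(x, cutoff = 1) {
  stop_if_not_ts(x)
  if (x$channel != "eda") stop("smooth_eda expects an eda channel")
  if (x$fs < 2 * cutoff) {
    stop(sprintf("sampling rate %g Hz is below 2 x cutoff (%g Hz)", x$fs, cutoff))
  }
  bf <- signal::butter(2, cutoff / (x$fs / 2))
  pad <- ceiling(3 * x$fs / cutoff)
  out <- filter_gapped(x$values, function(seg) filtfilt_padded(bf, seg, pad))
  phys_ts(out, fs = x$fs, start_time = x$start_time,
          units = x$units, channel = "eda")
}

#' Trough-to-peak SCR detection
#'
#' Classical trough-to-peak scoring of skin-conductance responses: each
#' local trough is paired with the next local peak of the smoothed signal,
#' and the pair is emitted as an SCR when the conductance rise is at least
#' `threshold` and the rise time lies within `[min_rise, max_rise]` seconds.
#' Events are returned in time order and never share a trough. Adding a
#' constant to the signal does not change the detected events.
#'
#' @param x a smoothed EDA [phys_ts()] at >= 16 Hz (lower rates work but are
#'   not recommended for rise-time resolution).
#' @param threshold minimum SCR amplitude in the signal's units
#'   (default 0.01 uS; an exploratory 0.001 is a common lower setting).
#' @param min_rise,max_rise admissible trough-to-peak rise time in seconds.
#' @return a data frame of class `scr_events` with columns `onset` (trough
#'   time), `peak` (peak time) and `amplitude` (peak minus trough value).
#' @export
detect_scrs_ttp <- function(x, threshold = 0.01, min_rise = 0.5, max_rise = 5) {
  stop_if_not_ts(x)
  v <- x$values
  t <- ts_times(x)
  peaks <- local_maxima(v)
  rows <- vector("list", length(peaks))
  for (i in seq_along(peaks)) {
    pk <- peaks[i]
    # the response onset (trough) is where the monotone rise into this
    # peak begins: walk back while the signal was strictly rising, then
    # trim the near-flat lead-in (increments below 1% of the threshold)
    tr <- pk
    while (tr > 1 && !is.na(v[tr - 1]) && v[tr - 1] < v[tr]) tr <- tr - 1L
    tol <- threshold / 100
    while (tr < pk - 1 && (v[tr + 1] - v[tr]) < tol) tr <- tr + 1L
    amp <- v[pk] - v[tr]
    rise <- t[pk] - t[tr]
    if (!is.na(amp) && amp >= threshold &&
        rise >= min_rise && rise <= max_rise) {
      rows[[i]] <- c(t[tr], t[pk], amp)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- data.frame(onset = numeric(0), peak = numeric(0),
                    amplitude = numeric(0))
  if (length(rows) > 0) {
    m <- do.call(rbind, rows)
    out <- data.frame(onset = m[, 1], peak = m[, 2], amplitude = m[, 3])
    # events are non-overlapping and never share a trough: an event whose
    # onset precedes the previous accepted peak is dropped
    if (nrow(out) > 1) {
      keep <- rep(TRUE, nrow(out))
      last_peak <- out$peak[1]
      for (i in 2:nrow(out)) {
        if (out$onset[i] < last_peak) keep[i] <- FALSE
        else last_peak <- out$peak[i]
      }
      out <- out[keep, , drop = FALSE]
    }
    rownames(out) <- NULL
  }
  class(out) <- c("scr_events", "data.frame")
  out
}

#' Per-window EDA parameters
#'
#' Aggregates a window of skin-conductance signal and its detected SCRs into
#' the three protocol parameters: mean skin-conductance level (SCL), SCR
#' rate per minute, and total SCR amplitude. The rate denominator is the
#' non-missing signal duration inside the window, so gaps do not deflate
#' rates.
#'
#' @param x the (smoothed) EDA [phys_ts()] the events were detected on.
#' @param events an `scr_events` data frame from [detect_scrs_ttp()].
#' @param window a list with `onset` and `offset` in seconds; defaults to
#'   the full span of `x`.
#' @return a list of class `eda_params`: `scl_mean`, `scr_per_min`,
#'   `total_amplitude`, `n_scr`, `window_length` (non-missing seconds).
#' @export
eda_parameters <- function(x, events, window = NULL) {
  stop_if_not_ts(x)
  if (is.null(window)) {
    window <- list(onset = x$start_time,
                   offset = x$start_time + ts_duration(x))
  }
  if (!(window$onset < window$offset)) stop("zero-length window")
  t <- ts_times(x)
  sel <- t >= window$onset - 1e-9 & t < window$offset - 1e-9
  if (!any(sel)) stop("window does not intersect the series")
  v <- x$values[sel]
  valid_s <- sum(!is.na(v)) / x$fs
  inwin <- events$onset >= window$onset - 1e-9 & events$onset < window$offset - 1e-9
  n_scr <- sum(inwin)
  total_amplitude <- sum(events$amplitude[inwin])
  structure(list(
    scl_mean = mean(v, na.rm = TRUE),
    scr_per_min = if (valid_s > 0) n_scr / (valid_s / 60) else NA_real_,
    total_amplitude = total_amplitude,
    n_scr = n_scr,
    window_length = valid_s
  ), class = "eda_params")
}

#' Flag an electrodermal nonresponder
#'
#' A participant whose whole recording contains no detectable SCR is flagged
#' as a nonresponder and excluded from cohort analyses. This is an automated
#' rule (zero detected SCRs) standing in for visual rater judgment.
#'
#' @param x the participant's EDA [phys_ts()] (full recording).
#' @param events full-recording `scr_events`.
#' @return list with `nonresponder` (logical) and `reason` (character).
#' @export
flag_nonresponder <- function(x, events) {
  n <- nrow(events)
  if (n == 0) {
    list(nonresponder = TRUE,
         reason = "no SCRs detected over the whole recording")
  } else {
    list(nonresponder = FALSE,
         reason = sprintf("%d SCRs detected", n))
  }
}
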