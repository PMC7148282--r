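#' Beat-time series
#'
#' Detected heart-beat times (R-peaks for ECG, pulse peaks for PPG) and the
#' successive-difference RR/PP intervals they induce. Interval `i` spans
#' `peak_times[i]` to `peak_times[i+1]`; [filter_intervals()] removes
#' physiologically implausible intervals from the interval multiset while
#' keeping the beats.
#'
#' @param peak_times strictly increasing beat times in seconds.
#' @param source `"ecg"` or `"ppg"`.
#' @param intervals optional interval vector; defaults to
#'   `diff(peak_times)`. After filtering, intervals no longer map 1:1 onto
#'   successive beats.
#' @param interval_starts start time of each interval; defaults to all but
#'   the last beat time. Kept in step with `intervals` by
#'   [filter_intervals()] so windowed parameters remain possible.
#' @return an object of class `beat_series`.
#' @export
beat_series <- function(peak_times, source = c("ecg", "ppg"),
                        intervals = NULL, interval_starts = NULL) {
  source <- match.arg(source)
  peak_times <- as.numeric(peak_times)
  if (length(peak_times) > 1 && any(diff(peak_times) <= 0)) {
    stop("peak_times must be strictly increasing")
  }
  if (is.null(intervals)) intervals <- diff(peak_times)
  if (is.null(interval_starts)) {
    interval_starts <- if (length(peak_times) > 1) {
      peak_times[-length(peak_times)]
    } else numeric(0)
  }
  if (length(interval_starts) != length(intervals)) {
    stop("intervals and interval_starts must have equal length")
  }
  structure(list(peak_times = peak_times, intervals = intervals,
                 interval_starts = interval_starts, source = source),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %s: %d beats, %d intervals", x$source,
              length(x$peak_times), length(x$intervals)))
  if (length(x$intervals) > 0) {
    cat(sprintf(", mean HR %.1f bpm", 60 / mean(x$intervals)))
  }
  cat("\n")
  invisible(x)
}

#' Read / write pre-detected beat times
#'
#' CSV with a `peak_time_s` column (and optionally `source`), allowing the
#' beat-detection step to be bypassed when a device exports beat times.
#' @param path file path.
#' @return a [beat_series()].
#' @export
read_beats_csv <- function(path) {
  if (!file.exists(path)) stop("beats file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!("peak_time_s" %in% names(d))) {
    stop("beats file must have column peak_time_s: ", path)
  }
  src <- if ("source" %in% names(d) && nrow(d) > 0) d$source[1] else "ecg"
  beat_series(sort(d$peak_time_s), source = src)
}

#' @rdname read_beats_csv
#' @param b a [beat_series()].
#' @export
write_beats_csv <- function(b, path) {
  write.csv(data.frame(peak_time_s = b$peak_times, source = b$source),
            path, row.names = FALSE)
  invisible(path)
}

#' Band-pass a cardiac signal (5-15 Hz)
#'
#' Zero-phase 2nd-order Butterworth band-pass isolating the QRS / pulse
#' energy band used for beat detection; drift and high-frequency noise are
#' removed.
#'
#' @param x an `ecg` or `ppg` [phys_ts()] with `fs >= 30` Hz (resample to
#'   200 Hz first for best results).
#' @param band lower/upper cutoff in Hz.
#' @return a filtered `phys_ts`.
#' @export
bandpass_cardiac <- function(x, band = c(5, 15)) {
  stop_if_not_ts(x)
  if (x$fs < 2 * band[2]) {
    stop(sprintf("sampling rate %g Hz is below 2 x %g Hz", x$fs, band[2]))
  }
  bf <- signal::butter(2, band / (x$fs / 2), type = "pass")
  pad <- ceiling(3 * x$fs / band[1])
  out <- filter_gapped(x$values, function(seg) filtfilt_padded(bf, seg, pad))
  phys_ts(out, fs = x$fs, start_time = x$start_time,
          units = x$units, channel = x$channel)
}

#' Detect beats in a band-passed cardiac signal
#'
#' ECG: adaptive-threshold R-peak detection on the rectified band-passed
#' signal (threshold tracks a rolling amplitude estimate), with a 0.25 s
#' refractory period. PPG: local-maxima detection with a prominence
#' threshold and the same refractory period. Returns peaks in time order;
#' an empty series is a valid result.
#'
#' @param x a band-passed [phys_ts()] (`ecg` or `ppg`).
#' @param refractory minimum peak spacing in seconds (default 0.25).
#' @return a [beat_series()].
#' @export
detect_beats <- function(x, refractory = 0.25) {
  stop_if_not_ts(x)
  if (!x$channel %in% c("ecg", "ppg")) {
    stop("detect_beats expects an ecg or ppg channel")
  }
  v <- x$values
  v[is.na(v)] <- 0
  if (all(v == 0) || sd(v) == 0) {
    return(beat_series(numeric(0), source = x$channel))
  }
  if (x$channel == "ecg") {
    env <- abs(v)
    thr <- 0.4 * quantile(env, 0.99, names = FALSE)
    cand <- local_maxima(env)
    cand <- cand[env[cand] >= thr]
    keep <- enforce_refractory(cand, env[cand], x$fs, refractory)
  } else {
    thr <- 0.3 * quantile(v[v > 0], 0.95, names = FALSE)
    cand <- local_maxima(v)
    cand <- cand[v[cand] >= thr]
    keep <- enforce_refractory(cand, v[cand], x$fs, refractory)
  }
  beat_series(ts_times(x)[keep], source = x$channel)
}

#' Remove implausible RR/PP intervals
#'
#' Deletes intervals shorter than `bounds[1]` or longer than `bounds[2]`
#' seconds from the interval multiset (boundary values are retained, beats
#' are kept). Idempotent; the removal count is attached as attribute
#' `n_removed` and reported via `message()`.
#'
#' @param b a [beat_series()].
#' @param bounds admissible interval range in seconds, default
#'   `c(0.33, 1.5)`.
#' @return a `beat_series` whose intervals all lie within `bounds`.
#' @export
filter_intervals <- function(b, bounds = c(0.33, 1.5)) {
  if (!inherits(b, "beat_series")) stop("expected a beat_series")
  ok <- b$intervals >= bounds[1] - 1e-9 & b$intervals <= bounds[2] + 1e-9
  n_removed <- sum(!ok)
  if (n_removed > 0) {
    message(sprintf("filter_intervals: removed %d of %d intervals outside [%g, %g] s",
                    n_removed, length(ok), bounds[1], bounds[2]))
  }
  out <- beat_series(b$peak_times, source = b$source,
                     intervals = b$intervals[ok],
                     interval_starts = b$interval_starts[ok])
  attr(out, "n_removed") <- n_removed
  out
}

#' Per-window signal quality index (0-100)
#'
#' Template-correlation SQI: within each window, every beat's waveform
#' segment is correlated with the window's average beat template; the SQI is
#' 100 x the mean correlation, multiplied by a plausibility factor that is 0
#' when the window's heart rate falls outside 40-180 bpm or the max/min
#' interval ratio exceeds 2.2. Windows with fewer than 3 beats score 0.
#'
#' When no waveform is available (`x = NULL`, e.g. device-exported beat
#' times), a beats-only surrogate is used: 100 x plausibility x a regularity
#' score `max(0, 1 - cv)` where `cv` is the coefficient of variation of the
#' window's intervals.
#'
#' @param x the cardiac [phys_ts()] the beats were detected on, or `NULL`.
#' @param b a [beat_series()].
#' @param window_len window length in seconds (default 10).
#' @param span optional `c(start, end)` to cover; defaults to the signal
#'   span (or the beat span when `x` is `NULL`).
#' @return data frame with columns `start`, `end`, `sqi`.
#' @export
sqi_windows <- function(x, b, window_len = 10, span = NULL) {
  if (!inherits(b, "beat_series")) stop("expected a beat_series")
  if (is.null(span)) {
    span <- if (!is.null(x)) {
      c(x$start_time, x$start_time + ts_duration(x))
    } else if (length(b$peak_times) > 0) {
      c(min(b$peak_times), max(b$peak_times))
    } else c(0, window_len)
  }
  starts <- seq(span[1], span[2] - 1e-9, by = window_len)
  res <- data.frame(start = starts, end = pmin(starts + window_len, span[2]),
                    sqi = 0)
  for (i in seq_len(nrow(res))) {
    pk <- b$peak_times[b$peak_times >= res$start[i] & b$peak_times < res$end[i]]
    if (length(pk) < 3) next
    iv <- diff(pk)
    hr <- 60 / mean(iv)
    plaus <- as.numeric(hr >= 40 && hr <= 180 && max(iv) / min(iv) <= 2.2)
    if (plaus == 0) next
    if (is.null(x)) {
      cv <- sd(iv) / mean(iv)
      res$sqi[i] <- 100 * plaus * max(0, 1 - cv)
    } else {
      half <- round(0.25 * x$fs)
      idx <- round((pk - x$start_time) * x$fs) + 1L
      segs <- lapply(idx, function(j) {
        lo <- j - half; hi <- j + half
        if (lo < 1 || hi > length(x$values)) return(NULL)
        s <- x$values[lo:hi]
        if (anyNA(s)) NULL else s
      })
      segs <- segs[!vapply(segs, is.null, logical(1))]
      if (length(segs) < 3) next
      m <- do.call(cbind, segs)
      templ <- rowMeans(m)
      if (sd(templ) == 0) next
      cors <- apply(m, 2, function(s) {
        if (sd(s) == 0) 0 else cor(s, templ)
      })
      res$sqi[i] <- 100 * plaus * max(0, mean(cors))
    }
  }
  res
}

#' Quality gate for a block
#'
#' A block is accepted when a *consecutive* run of quality windows at or
#' above the SQI threshold covers at least `min_coverage` of the block.
#' Longer blocks (baseline/stressor) use `sqi_long` (default 70); short
#' event windows use the stricter `sqi_event` (default 80).
#'
#' @param windows a data frame from [sqi_windows()].
#' @param block list with `onset`, `offset` seconds.
#' @param gate list with `min_coverage` (default 0.5), `sqi_long` (70),
#'   `sqi_event` (80); see [default_config()].
#' @param event logical: apply the event-level threshold?
#' @return list with `accepted` (logical), `coverage` (fraction of the block
#'   covered by the best consecutive accepted run) and `threshold` used.
#' @export
gate_block <- function(windows, block,
                       gate = list(min_coverage = 0.5, sqi_long = 70,
                                   sqi_event = 80),
                       event = FALSE) {
  thr <- if (event) gate$sqi_event else gate$sqi_long
  blen <- block$offset - block$onset
  # windows overlapping the block, clipped to it
  ov <- windows[windows$end > block$onset & windows$start < block$offset, ,
                drop = FALSE]
  if (nrow(ov) == 0) {
    return(list(accepted = FALSE, coverage = 0, threshold = thr))
  }
  ov$start <- pmax(ov$start, block$onset)
  ov$end <- pmin(ov$end, block$offset)
  good <- ov$sqi >= thr
  # longest consecutive accepted run, in covered seconds
  best <- 0; cur <- 0
  for (i in seq_len(nrow(ov))) {
    if (good[i]) {
      cur <- cur + (ov$end[i] - ov$start[i])
      best <- max(best, cur)
    } else cur <- 0
  }
  cov <- best / blen
  list(accepted = cov >= gate$min_coverage, coverage = cov, threshold = thr)
}

#' Time-domain cardiovascular parameters
#'
#' Mean heart rate, interval standard deviation and RMSSD over the intervals
#' whose starting beat falls inside the window. RMSSD follows
#' `sqrt( (1/(N-1)) * sum_{i=1}^{N-1} (I[i+1] - I[i])^2 )`
#' with `N` the number of intervals (so `N - 1` successive differences).
#' Insufficient intervals yield `NA` parameters, never silent zeros.
#'
#' @param b a (filtered) [beat_series()].
#' @param window optional list with `onset`, `offset` seconds; default all.
#' @return list of class `cva_params`: `mean_hr` (bpm), `sd_interval` (s),
#'   `rmssd` (s), `n_intervals`.
#' @export
cva_parameters <- function(b, window = NULL) {
  if (!inherits(b, "beat_series")) stop("expected a beat_series")
  iv <- b$intervals
  if (!is.null(window)) {
    sel <- b$interval_starts >= window$onset - 1e-9 &
      b$interval_starts < window$offset - 1e-9
    iv <- iv[sel]
  }
  n <- length(iv)
  if (n < 2) {
    return(structure(list(mean_hr = NA_real_, sd_interval = NA_real_,
                          rmssd = NA_real_, n_intervals = n),
                     class = "cva_params"))
  }
  d <- diff(iv)
  structure(list(
    mean_hr = 60 / mean(iv),
    sd_interval = sd(iv),
    rmssd = sqrt(sum(d^2) / (n - 1)),
    n_intervals = n
  ), class = "cva_params")
}
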