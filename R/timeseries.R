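#' Uniformly sampled physiological time series
#'
#' The basic container shared by every stage of the protocol: a uniformly
#' sampled signal with an explicit start time and sampling rate. Timestamps
#' are implied as `start_time + (i - 1) / fs` (seconds from recording start).
#' Missing samples are encoded as `NA` and are never silently dropped;
#' downstream operations document how they propagate.
#'
#' @param values numeric vector of samples; `NA` marks a missing sample.
#' @param fs sampling rate in Hz, must be positive.
#' @param start_time time of the first sample in seconds from recording start.
#' @param units unit string, e.g. `"uS"`, `"mV"`, `"a.u."`.
#' @param channel one of `"eda"`, `"ecg"`, `"ppg"`.
#' @return an object of class `phys_ts`.
#' @examples
#' x <- phys_ts(sin(seq(0, 2 * pi, length.out = 64)), fs = 16, channel = "eda")
#' ts_duration(x)
#' @export
phys_ts <- function(values, fs, start_time = 0, units = "a.u.",
                    channel = c("eda", "ecg", "ppg")) {
  channel <- match.arg(channel)
  if (!is.numeric(fs) || length(fs) != 1 || is.na(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)")
  }
  if (!is.numeric(values)) stop("`values` must be numeric")
  structure(
    list(values = as.numeric(values), fs = as.numeric(fs),
         start_time = as.numeric(start_time), units = units,
         channel = channel),
    class = "phys_ts"
  )
}

#' @export
print.phys_ts <- function(x, ...) {
  n_na <- sum(is.na(x$values))
  cat(sprintf("<phys_ts> %s, %g Hz, %d samples (%.1f s), start %.2f s, units %s",
              x$channel, x$fs, length(x$values),
              length(x$values) / x$fs, x$start_time, x$units))
  if (n_na > 0) cat(sprintf(", %d missing", n_na))
  cat("\n")
  invisible(x)
}

#' Sample timestamps of a series
#' @param x a `phys_ts`.
#' @return numeric vector of times in seconds from recording start.
#' @export
ts_times <- function(x) {
  x$start_time + (seq_along(x$values) - 1) / x$fs
}

#' Duration of a series in seconds
#' @param x a `phys_ts`.
#' @return duration `length(values) / fs` in seconds.
#' @export
ts_duration <- function(x) length(x$values) / x$fs

stop_if_not_ts <- function(x) {
  if (!inherits(x, "phys_ts")) stop("expected a `phys_ts` object")
  invisible(x)
}

#' Resample a series to a target rate
#'
#' Up-sampling uses linear interpolation; down-sampling applies a zero-phase
#' anti-alias low-pass (2nd-order Butterworth at 0.45 x target rate, run
#' forwards and backwards) before interpolating onto the coarser grid.
#' Duration is preserved to within one sample period. Missing samples
#' propagate: an output sample is `NA` whenever a missing input sample lies
#' within half an input period of it or interpolation would bridge a gap.
#'
#' @param x a `phys_ts`.
#' @param target_fs target sampling rate in Hz.
#' @return a `phys_ts` at `target_fs` covering the same span.
#' @examples
#' x <- phys_ts(rnorm(240), fs = 4, channel = "eda")
#' y <- resample_to(x, 16)
#' length(y$values) # 960
#' @export
resample_to <- function(x, target_fs) {
  stop_if_not_ts(x)
  if (!is.numeric(target_fs) || length(target_fs) != 1 || target_fs <= 0) {
    stop("`target_fs` must be a single positive number (Hz)")
  }
  if (target_fs == x$fs) return(x)
  n_in <- length(x$values)
  if (n_in < 2) stop("need at least 2 samples to resample")
  t_in <- ts_times(x)
  v <- x$values
  na_in <- is.na(v)

  if (target_fs < x$fs) {
    # anti-alias low-pass before decimation; filter only over non-missing runs
    cutoff <- 0.45 * target_fs
    bf <- signal::butter(2, cutoff / (x$fs / 2))
    pad <- ceiling(3 * x$fs / cutoff)
    v <- filter_gapped(v, function(seg) filtfilt_padded(bf, seg, pad))
  }

  n_out <- max(2L, round(n_in * target_fs / x$fs))
  t_out <- x$start_time + (seq_len(n_out) - 1) / target_fs

  ok <- !is.na(v)
  if (sum(ok) < 2) stop("fewer than 2 non-missing samples; cannot resample")
  out <- approx(t_in[ok], v[ok], xout = t_out, rule = 2)$y

  # propagate gaps: mark output NA where the bracketing input samples are
  # not adjacent non-missing samples (i.e. interpolation bridged a gap)
  if (any(na_in)) {
    gap_t <- t_in[na_in]
    half <- 0.5 / x$fs
    for (g in gap_t) {
      out[t_out >= g - half - 1e-9 & t_out <= g + half + 1e-9] <- NA
    }
  }
  phys_ts(out, fs = target_fs, start_time = x$start_time,
          units = x$units, channel = x$channel)
}

# apply `fun` separately to each maximal non-NA run of at least 2 samples;
# shorter runs and NA positions pass through unchanged / as NA
filter_gapped <- function(v, fun) {
  ok <- !is.na(v)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- v
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= 8) {
      seg <- v[starts[k]:ends[k]]
      out[starts[k]:ends[k]] <- fun(seg)
    }
  }
  out
}

#' Remove the least-squares linear trend
#'
#' Fits a single straight line to the non-missing samples by ordinary least
#' squares and subtracts it from the whole series (a stationarity
#' prerequisite for cross-correlation). `NA` samples stay `NA`.
#'
#' @param x a `phys_ts` with at least 2 non-missing samples.
#' @return detrended `phys_ts`; the best-fit slope of the result is ~0.
#' @export
detrend_linear <- function(x) {
  stop_if_not_ts(x)
  ok <- !is.na(x$values)
  if (sum(ok) < 2) stop("detrend_linear: fewer than 2 non-missing samples")
  t <- ts_times(x)
  fit <- lm.fit(cbind(1, t[ok]), x$values[ok])
  b <- fit$coefficients
  out <- x$values - (b[1] + b[2] * t)
  phys_ts(out, fs = x$fs, start_time = x$start_time,
          units = x$units, channel = x$channel)
}

#' Z-normalize a series
#'
#' Centers and scales to unit sample standard deviation over the non-missing
#' samples, making two signals comparable irrespective of offset and gain.
#'
#' @param x a `phys_ts` with positive sample variance.
#' @return normalized `phys_ts` (units become `"z"`).
#' @export
znormalize <- function(x) {
  stop_if_not_ts(x)
  v <- x$values
  mu <- mean(v, na.rm = TRUE)
  s <- sd(v, na.rm = TRUE)
  if (!is.finite(s) || s <= 0) {
    stop(sprintf("znormalize: zero variance in channel '%s'", x$channel))
  }
  phys_ts((v - mu) / s, fs = x$fs, start_time = x$start_time,
          units = "z", channel = x$channel)
}

#' Slice a block out of a series
#'
#' Returns the samples with `onset <= t < offset` (half-open, so adjacent
#' blocks partition a recording without sharing a sample). The slice keeps
#' the block onset as its start time.
#'
#' @param x a `phys_ts`.
#' @param block a list or one-row data frame with `onset` and `offset`
#'   (seconds), e.g. a row of an [event_schedule()] blocks table.
#' @return a `phys_ts` covering the block.
#' @export
slice_block <- function(x, block) {
  stop_if_not_ts(x)
  onset <- block$onset; offset <- block$offset
  if (is.null(onset) || is.null(offset) || !(onset < offset)) {
    stop("block must have onset < offset")
  }
  t <- ts_times(x)
  sel <- t >= onset - 1e-9 & t < offset - 1e-9
  if (!any(sel)) stop("slice_block: block does not intersect the series span")
  phys_ts(x$values[sel], fs = x$fs, start_time = t[which(sel)[1]],
          units = x$units, channel = x$channel)
}
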