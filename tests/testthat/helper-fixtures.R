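# fixtures built in code; no stored data

sine_ts <- function(freq, fs, dur, amp = 1, phase = 0, channel = "eda") {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  phys_ts(amp * sin(2 * pi * freq * t + phase), fs = fs, channel = channel)
}

# baseline plus smooth gaussian bumps at given onset times/amplitudes;
# gaussian sd 0.8 s gives a trough-to-peak rise of ~1.6 s, inside the
# admissible 0.5-5 s window
bumpy_eda <- function(onsets, amps, fs = 16, dur = 60, baseline = 2) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  v <- rep(baseline, length(t))
  for (i in seq_along(onsets)) {
    v <- v + amps[i] * exp(-((t - onsets[i]) / 0.8)^2 / 2)
  }
  phys_ts(v, fs = fs, channel = "eda")
}

# independent trough-to-peak oracle: measured rise of each bump on the
# constructed signal itself (local min before the bump vs max after)
bump_rise <- function(x, onset, halfwidth = 3) {
  t <- ts_times(x)
  pre <- x$values[t >= onset - halfwidth & t <= onset]
  post <- x$values[t >= onset - halfwidth & t <= onset + halfwidth]
  max(post) - min(pre)
}

# regular beat train with given interval
beat_train <- function(interval, dur, start = 0.5, source = "ecg") {
  beat_series(seq(start, dur, by = interval), source = source)
}

# brute-force RMSSD straight from the printed formula
rmssd_brute <- function(iv) {
  n <- length(iv)
  acc <- 0
  for (i in seq_len(n - 1)) acc <- acc + (iv[i + 1] - iv[i])^2
  sqrt(acc / (n - 1))
}

tiny_schedule <- function(pid = "P1") {
  event_schedule(pid, data.frame(
    label = c("base", "stress", "recover"),
    kind = c("baseline", "stressor", "recovery"),
    onset = c(0, 60, 90), offset = c(60, 90, 150)))
}

skip_msgs <- function(expr) suppressMessages(expr)
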