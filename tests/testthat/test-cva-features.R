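test_that("the cardiac band-pass keeps beat-band energy and kills drift", {
  t <- seq(0, 20 - 1 / 200, by = 1 / 200)
  mid <- 1000:3000
  s10 <- phys_ts(sin(2 * pi * 10 * t), fs = 200, channel = "ecg")
  expect_gt(max(abs(bandpass_cardiac(s10)$values[mid])), 0.7)

  drift <- phys_ts(sin(2 * pi * 0.5 * t), fs = 200, channel = "ecg")
  expect_lt(max(abs(bandpass_cardiac(drift)$values[mid])), 0.1)

  zero <- phys_ts(rep(0, 4000), fs = 200, channel = "ecg")
  expect_equal(bandpass_cardiac(zero)$values, rep(0, 4000))

  expect_error(bandpass_cardiac(phys_ts(rnorm(100), fs = 20,
                                        channel = "ecg")), "below 2 x")
})

test_that("beat detection counts impulse trains and PPG pulses correctly", {
  truth <- beat_train(1, 60)
  ecg <- bandpass_cardiac(render_ecg(truth, fs = 200, duration = 60.5))
  b <- detect_beats(ecg)
  expect_true(abs(length(b$peak_times) - length(truth$peak_times)) <= 1)

  flat <- phys_ts(rep(0, 2000), fs = 200, channel = "ecg")
  expect_equal(length(detect_beats(flat)$peak_times), 0)

  ppg75 <- beat_train(0.8, 60, source = "ppg")
  wav <- render_ppg(ppg75, fs = 64, duration = 60.5)
  bp <- detect_beats(wav)
  expect_lt(abs(mean(bp$intervals) - 0.8), 0.01)
})

test_that("interval filtering deletes exactly the out-of-range intervals", {
  pk <- cumsum(c(0.5, 0.2, 0.8, 1.6, 1.0))
  b <- beat_series(pk)
  expect_equal(b$intervals, c(0.2, 0.8, 1.6, 1.0))
  f <- skip_msgs(filter_intervals(b))
  expect_equal(f$intervals, c(0.8, 1.0))
  expect_equal(attr(f, "n_removed"), 2)

  edge <- beat_series(cumsum(c(0.5, 0.33, 1.5)))
  fe <- skip_msgs(filter_intervals(edge))
  expect_equal(fe$intervals, c(0.33, 1.5))

  # idempotent, and output always satisfies the invariant
  ff <- skip_msgs(filter_intervals(f))
  expect_equal(ff$intervals, f$intervals)
  set.seed(5)
  rnd <- beat_series(cumsum(runif(200, 0.1, 2)))
  fr <- skip_msgs(filter_intervals(rnd))
  expect_true(all(fr$intervals >= 0.33 & fr$intervals <= 1.5))
})

test_that("RMSSD follows the printed formula exactly", {
  const <- beat_train(0.8, 60)
  p <- cva_parameters(const)
  expect_equal(p$mean_hr, 75)
  expect_equal(p$sd_interval, 0)
  expect_equal(p$rmssd, 0)

  two <- beat_series(cumsum(c(0.5, 0.8, 0.9)))
  expect_equal(cva_parameters(two)$rmssd, 0.1, tolerance = 1e-12)

  set.seed(11)
  iv <- runif(1000, 0.5, 1.2)
  b <- beat_series(cumsum(c(0.3, iv)))
  expect_equal(cva_parameters(b)$rmssd, rmssd_brute(iv), tolerance = 1e-12)

  # insufficient intervals are NA, never zero
  p1 <- cva_parameters(beat_series(c(1, 1.8)),
                       window = list(onset = 0, offset = 0.5))
  expect_true(is.na(p1$mean_hr))
})

test_that("interval statistics are translation-invariant and scale-equivariant", {
  set.seed(3)
  iv <- runif(300, 0.6, 1.0)
  b1 <- beat_series(cumsum(c(0, iv)))
  b2 <- beat_series(cumsum(c(100, iv)))  # shifted beat times
  p1 <- cva_parameters(b1); p2 <- cva_parameters(b2)
  expect_equal(p1$rmssd, p2$rmssd)
  expect_equal(p1$sd_interval, p2$sd_interval)

  b3 <- beat_series(cumsum(c(0, 1.3 * iv)))
  p3 <- cva_parameters(b3)
  expect_equal(p3$rmssd, 1.3 * p1$rmssd, tolerance = 1e-12)
  expect_equal(p3$sd_interval, 1.3 * p1$sd_interval, tolerance = 1e-12)
})

test_that("quality windows score clean beats high, noise low, sparse zero", {
  clean <- beat_train(0.8, 60, source = "ppg")
  wav <- render_ppg(clean, fs = 64, duration = 60)
  b <- detect_beats(wav)
  q <- sqi_windows(wav, b)
  expect_true(all(q$sqi[1:5] > 90))

  set.seed(9)
  noise <- phys_ts(rnorm(64 * 60), fs = 64, channel = "ppg")
  bn <- detect_beats(noise)
  qn <- sqi_windows(noise, bn)
  expect_lt(mean(qn$sqi), 30)

  sparse <- beat_series(c(1, 2), source = "ppg")
  qs <- sqi_windows(NULL, sparse, span = c(0, 10))
  expect_true(all(qs$sqi == 0))
})

test_that("the quality gate requires a consecutive covered run", {
  win <- data.frame(start = seq(0, 30, by = 5), end = seq(5, 35, by = 5),
                    sqi = 90)
  blk <- list(onset = 0, offset = 35)
  g <- gate_block(win, blk)
  expect_true(g$accepted)
  expect_equal(g$coverage, 1.0)

  # alternating 5 s good/bad: half covered but never consecutively
  alt <- win; alt$sqi <- rep(c(90, 10), length.out = nrow(alt))
  ga <- gate_block(alt, blk)
  expect_false(ga$accepted)
  expect_lt(ga$coverage, 0.5)

  # beep windows use the stricter event threshold
  w75 <- data.frame(start = 0, end = 5, sqi = 75)
  beep <- list(onset = 0, offset = 5)
  expect_true(gate_block(w75, beep, event = FALSE)$accepted)
  expect_false(gate_block(w75, beep, event = TRUE)$accepted)

  # gating monotonicity: lowering thresholds never rejects an accepted block
  set.seed(21)
  for (i in 1:20) {
    w <- data.frame(start = seq(0, 30, by = 5), end = seq(5, 35, by = 5),
                    sqi = runif(7, 0, 100))
    hi <- gate_block(w, blk, gate = list(min_coverage = 0.5, sqi_long = 70,
                                         sqi_event = 80))
    lo <- gate_block(w, blk, gate = list(min_coverage = 0.5, sqi_long = 50,
                                         sqi_event = 60))
    if (hi$accepted) expect_true(lo$accepted)
  }
})

test_that("generated beat series recover their configured targets", {
  cfg <- synth_config(n_participants = 1, seed = 99,
                      effects = list(ssst_hr_delta = 0))
  sch <- generate_schedule(cfg)
  est <- sapply(1:8, function(i) {
    p <- simulate_cva_pair(cfg, sch, 1000 + i)
    u <- cva_parameters(p$rd)
    c(u$mean_hr, u$sd_interval, u$rmssd)
  })
  m <- rowMeans(est)
  expect_lt(abs(m[1] - 70) / 70, 0.05)
  expect_lt(abs(m[2] - 0.05) / 0.05, 0.10)
  expect_lt(abs(m[3] - 0.04) / 0.04, 0.10)
})
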