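test_that("EDA smoothing preserves DC, kills high frequency, and barely overshoots", {
  flat <- phys_ts(rep(2, 16 * 60), fs = 16, units = "uS", channel = "eda")
  out <- smooth_eda(flat)
  expect_lt(abs(mean(out$values) - 2), 1e-6)

  s5 <- sine_ts(5, 16, 10)
  g <- max(abs(smooth_eda(s5)$values[40:120]))
  expect_lt(g, 0.1)  # > 90% attenuation

  step <- phys_ts(c(rep(0, 200), rep(1, 400)), fs = 16, channel = "eda")
  sm <- smooth_eda(step)$values
  expect_lt(max(sm) - 1, 0.05)
  expect_gt(min(sm), -0.05)

  expect_error(smooth_eda(phys_ts(rep(1, 10), fs = 1.5, channel = "eda")),
               "below 2 x cutoff")
  expect_error(smooth_eda(sine_ts(1, 64, 2, channel = "ecg")), "eda channel")
})

test_that("trough-to-peak detection finds exactly the supra-threshold bumps", {
  flat <- phys_ts(rep(2, 16 * 60), fs = 16, units = "uS", channel = "eda")
  expect_equal(nrow(detect_scrs_ttp(flat)), 0)

  x <- bumpy_eda(onsets = c(15, 30, 45), amps = c(0.5, 0.05, 0.005))
  # oracle: direct trough/peak differencing on the constructed signal
  rises <- vapply(c(15, 30, 45), function(o) bump_rise(x, o), numeric(1))
  expect_true(rises[1] > 0.4 && rises[2] > 0.04 && rises[3] < 0.01)
  ev <- detect_scrs_ttp(smooth_eda(x))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$peak, c(15, 30), tolerance = 0.3)
  expect_true(all(ev$onset < ev$peak))
  expect_true(all(ev$peak - ev$onset <= 5))

  one <- bumpy_eda(onsets = 20, amps = 0.5)
  ev1 <- detect_scrs_ttp(smooth_eda(one))
  expect_equal(nrow(ev1), 1)
  expect_lt(abs(ev1$amplitude - 0.5), 0.02)
})

test_that("detection is invariant to constant offsets and recalls injected bumps", {
  set.seed(42)
  onsets <- sort(runif(8, 5, 290))
  onsets <- onsets[c(TRUE, diff(onsets) > 8)]
  amps <- runif(length(onsets), 0.02, 0.6)  # all >= 2x threshold
  x <- bumpy_eda(onsets, amps, dur = 300)
  ev <- detect_scrs_ttp(smooth_eda(x))
  expect_equal(nrow(ev), length(onsets))

  shifted <- phys_ts(x$values + 5, fs = x$fs, units = "uS", channel = "eda")
  ev2 <- detect_scrs_ttp(smooth_eda(shifted))
  expect_equal(ev2$onset, ev$onset)
  expect_equal(ev2$amplitude, ev$amplitude, tolerance = 1e-9)

  # sub-threshold bumps are never detected
  sub <- bumpy_eda(onsets, rep(0.005, length(onsets)), dur = 300)
  expect_equal(nrow(detect_scrs_ttp(smooth_eda(sub))), 0)
})

test_that("window parameters follow the defining arithmetic", {
  flat <- phys_ts(rep(2, 16 * 60), fs = 16, units = "uS", channel = "eda")
  none <- detect_scrs_ttp(flat)
  p <- eda_parameters(flat, none)
  expect_equal(p$scl_mean, 2)
  expect_equal(p$n_scr, 0)
  expect_equal(p$total_amplitude, 0)

  ev <- data.frame(onset = c(10, 70), peak = c(12, 72),
                   amplitude = c(0.5, 0.3))
  x <- phys_ts(rep(1, 16 * 120), fs = 16, units = "uS", channel = "eda")
  p2 <- eda_parameters(x, ev, list(onset = 0, offset = 120))
  expect_equal(p2$n_scr, 2)
  expect_equal(p2$total_amplitude, 0.8)
  expect_equal(p2$scr_per_min, 1.0)

  # 50% missing halves the rate denominator
  v <- rep(1, 16 * 120); v[1:(16 * 60)] <- NA
  gap <- phys_ts(v, fs = 16, units = "uS", channel = "eda")
  ev1 <- data.frame(onset = 100, peak = 102, amplitude = 0.5)
  p3 <- eda_parameters(gap, ev1, list(onset = 0, offset = 120))
  expect_equal(p3$scr_per_min, 1 / (60 / 60))

  expect_error(eda_parameters(x, ev, list(onset = 5, offset = 5)),
               "zero-length")
})

test_that("total amplitude is additive over a window partition", {
  set.seed(7)
  ev <- data.frame(onset = sort(runif(20, 0, 300)), peak = NA,
                   amplitude = runif(20, 0.05, 0.5))
  ev$peak <- ev$onset + 1
  x <- phys_ts(rep(1, 16 * 300), fs = 16, units = "uS", channel = "eda")
  whole <- eda_parameters(x, ev, list(onset = 0, offset = 300))
  parts <- lapply(list(c(0, 120), c(120, 200), c(200, 300)), function(w) {
    eda_parameters(x, ev, list(onset = w[1], offset = w[2]))
  })
  expect_equal(sum(vapply(parts, `[[`, numeric(1), "total_amplitude")),
               whole$total_amplitude, tolerance = 1e-12)
  expect_equal(sum(vapply(parts, `[[`, numeric(1), "n_scr")), whole$n_scr)
})

test_that("nonresponders are flagged on zero SCRs and excluded downstream", {
  flat <- phys_ts(rep(2, 16 * 60), fs = 16, units = "uS", channel = "eda")
  none <- detect_scrs_ttp(flat)
  expect_true(flag_nonresponder(flat, none)$nonresponder)

  one <- data.frame(onset = 10, peak = 12, amplitude = 0.5)
  expect_false(flag_nonresponder(flat, one)$nonresponder)

  # cohort of 10 with 2 flat members retains 8
  cfg <- synth_config(n_participants = 10, seed = 3,
                      eda = list(nonresponder_fraction = 0.2))
  recs <- simulate_cohort(cfg)
  res <- suppressMessages(run_protocol(recs, levels = "signal",
                                       channels = "eda"))
  expect_equal(length(res$signal$best_r), 8)
  expect_equal(sum(grepl("nonresponder", res$exclusions)), 2)
})
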