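smooth_fixture <- function(n, fs = 16, seed = 1) {
  set.seed(seed)
  v <- stats::filter(rnorm(n + 200), rep(1 / 40, 40), sides = 2)
  v <- v[!is.na(v)][1:n]
  phys_ts(as.numeric(v), fs = fs, channel = "eda")
}

test_that("cross-correlation recovers identity, shifts, and stays honest on noise", {
  x <- znormalize(detrend_linear(smooth_fixture(1200)))
  r0 <- cross_correlation_lags(x, x)
  expect_equal(r0$best_lag, 0)
  expect_equal(r0$best_r, 1.0, tolerance = 1e-12)

  # y delayed by 3 samples: y[i] = x[i - 3]
  n <- length(x$values)
  y <- phys_ts(c(x$values[1:3], x$values[1:(n - 3)]), fs = 16,
               channel = "eda")
  r3 <- cross_correlation_lags(x, znormalize(detrend_linear(y)), max_lag = 8)
  expect_equal(r3$best_lag, 3)
  expect_gt(r3$best_r, 0.99)

  set.seed(2)
  a <- phys_ts(rnorm(1000), fs = 16, channel = "eda")
  b <- phys_ts(rnorm(1000), fs = 16, channel = "eda")
  rn <- cross_correlation_lags(znormalize(a), znormalize(b))
  expect_lt(abs(rn$best_r), 0.15)
})

test_that("per-lag correlations match a direct Pearson computation", {
  x <- smooth_fixture(500, seed = 4)
  y <- smooth_fixture(500, seed = 5)
  res <- cross_correlation_lags(x, y, max_lag = 8)
  n <- 500
  for (k in c(-8, -3, 0, 2, 8)) {
    if (k >= 0) {
      direct <- cor(x$values[1:(n - k)], y$values[(1 + k):n])
    } else {
      direct <- cor(x$values[(1 - k):n], y$values[1:(n + k)])
    }
    expect_equal(res$r_by_lag[res$lags == k], direct, tolerance = 1e-12)
  }
  # antisymmetry r_xy(k) = r_yx(-k)
  rev <- cross_correlation_lags(y, x, max_lag = 8)
  expect_equal(res$r_by_lag, rev$r_by_lag[order(-rev$lags)],
               tolerance = 1e-12)
})

test_that("lag counts convert to seconds by lag / fs", {
  expect_equal(lag_duration(8, 16), 0.5)
  expect_equal(lag_duration(1, 4), 0.25)
  expect_equal(lag_duration(16, 16), 1)
  expect_equal(lag_duration(0, 123), 0)
  expect_error(lag_duration(1, 0), "positive")
})

test_that("the cohort passes only when every participant clears the threshold", {
  mk <- function(r, lag = 0) {
    structure(list(participant_id = "x", lags = -8:8,
                   r_by_lag = rep(NA, 17), best_lag = lag, best_r = r),
              class = "crosscorr_result")
  }
  pass <- cohort_signal_decision(list(mk(0.85), mk(0.90), mk(0.95)))
  expect_true(pass$pass)

  fail <- cohort_signal_decision(list(mk(0.85), mk(0.70)))
  expect_false(fail$pass)

  syst <- cohort_signal_decision(list(mk(0.9, 2), mk(0.85, 2), mk(0.95, 2)))
  expect_equal(syst$systematic_lag, 2L)
  mixed <- cohort_signal_decision(list(mk(0.9, -1), mk(0.85, 2), mk(0.95, 0)))
  expect_null(mixed$systematic_lag)
})

test_that("bias adjustment recenters and rescales only after a signal pass", {
  x <- smooth_fixture(2000, seed = 6)
  pass <- cohort_signal_decision(list(structure(
    list(participant_id = "p", lags = -8:8, r_by_lag = rep(NA, 17),
         best_lag = 0, best_r = 0.95), class = "crosscorr_result")))

  y1 <- phys_ts(x$values + 1, fs = 16, channel = "eda")
  a1 <- mean_bias_adjust(x, y1, pass)
  expect_equal(a1$bias, 1.0, tolerance = 1e-9)
  expect_equal(a1$adjusted$values, x$values, tolerance = 1e-9)

  y2 <- phys_ts(2 * x$values, fs = 16, channel = "eda")
  a2 <- mean_bias_adjust(x, y2, pass)
  expect_equal(a2$variance_ratio, 4.0, tolerance = 1e-9)
  expect_equal(a2$adjusted$values, x$values, tolerance = 1e-9)

  set.seed(8)
  y3 <- phys_ts(1.5 * x$values + 0.3 + rnorm(2000, 0, 0.01), fs = 16,
                channel = "eda")
  a3 <- mean_bias_adjust(x, y3, pass)
  expect_equal(a3$bias, mean(y3$values - x$values), tolerance = 1e-9)
  expect_lt(abs(sqrt(a3$variance_ratio) - 1.5), 0.05)

  failv <- cohort_signal_decision(list(structure(
    list(participant_id = "p", lags = -8:8, r_by_lag = rep(NA, 17),
         best_lag = 0, best_r = 0.5), class = "crosscorr_result")))
  expect_error(mean_bias_adjust(x, y1, failv), "passing")
})

test_that("injected wearable lags are recovered end to end", {
  cfg <- synth_config(n_participants = 1, seed = 31,
                      eda = list(wearable_lag = 3, noise_sd = 0.002))
  sch <- generate_schedule(cfg)
  pair <- simulate_eda_pair(cfg, sch, 555)
  rd16 <- resample_to(pair$rd, 16)
  wd16 <- resample_to(pair$wd, 16)
  r <- cross_correlation_lags(znormalize(detrend_linear(rd16)),
                              znormalize(detrend_linear(wd16)))
  expect_equal(r$best_lag, 3)
  expect_gt(r$best_r, 0.95)
})
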