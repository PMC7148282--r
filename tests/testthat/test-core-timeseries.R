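test_that("resampling preserves duration and recovers band-limited content", {
  x <- phys_ts(rnorm(240), fs = 4, channel = "eda")
  y <- resample_to(x, 16)
  expect_equal(y$fs, 16)
  expect_equal(length(y$values), 960)
  expect_equal(ts_duration(y), ts_duration(x))

  # identity
  expect_identical(resample_to(x, 4), x)

  # pure slow sinusoid survives 256 -> 16 Hz within 1e-3 of amplitude
  t <- seq(0, 60 - 1 / 256, by = 1 / 256)
  s <- phys_ts(sin(2 * pi * 0.1 * t), fs = 256, channel = "eda")
  d <- resample_to(s, 16)
  expect_lt(max(abs(d$values - sin(2 * pi * 0.1 * ts_times(d)))), 1e-3)

  expect_error(resample_to(x, 0), "positive")
  expect_error(resample_to(x, -2), "positive")
})

test_that("up-then-down resampling round-trips band-limited fixtures", {
  fs <- 16
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  x <- phys_ts(sin(2 * pi * 0.005 * t) + 0.5 * cos(2 * pi * 0.008 * t),
               fs = fs, channel = "eda")
  y <- resample_to(resample_to(x, 2 * fs), fs)
  # one-second margins: boundary samples carry residual filter-edge error
  m <- fs
  idx <- (m + 1):(length(t) - m)
  expect_lt(max(abs(y$values[idx] - x$values[idx])), 1e-6)
})

test_that("missing samples propagate through resampling as gaps", {
  v <- sin(seq(0, 20, length.out = 320))
  v[100:140] <- NA
  x <- phys_ts(v, fs = 16, channel = "eda")
  y <- resample_to(x, 32)
  t_gap <- ts_times(x)[100:140]
  t_out <- ts_times(y)
  inside <- t_out > min(t_gap) & t_out < max(t_gap)
  expect_true(all(is.na(y$values[inside])))
  expect_false(anyNA(y$values[t_out < min(t_gap) - 0.1]))
})

test_that("linear detrending removes exactly the least-squares line", {
  t <- seq(0, 59.75, by = 0.25)
  line <- phys_ts(2 + 3 * t, fs = 4, channel = "eda")
  out <- detrend_linear(line)
  expect_lt(max(abs(out$values)), 1e-9)

  const <- phys_ts(rep(5, 100), fs = 4, channel = "eda")
  expect_lt(max(abs(detrend_linear(const)$values)), 1e-9)

  # sin(t): compare against an independently fitted line
  s <- phys_ts(sin(t), fs = 4, channel = "eda")
  fit <- lm(sin(t) ~ t)
  expected <- sin(t) - fitted(fit)
  expect_equal(detrend_linear(s)$values, unname(expected), tolerance = 1e-12)

  # residual slope is ~0
  out2 <- detrend_linear(s)
  expect_lt(abs(coef(lm(out2$values ~ t))[2]), 1e-9)

  allna <- phys_ts(rep(NA_real_, 10), fs = 4, channel = "eda")
  expect_error(detrend_linear(allna), "non-missing")
})

test_that("z-normalization centers, scales, and is idempotent and affine-invariant", {
  x <- phys_ts(c(1, 2, 3), fs = 1, channel = "eda")
  z <- znormalize(x)
  expect_lt(abs(mean(z$values)), 1e-9)
  expect_lt(abs(sd(z$values) - 1), 1e-9)

  expect_equal(znormalize(z)$values, z$values, tolerance = 1e-9)

  set.seed(1)
  v <- rnorm(200)
  a <- phys_ts(v, fs = 4, channel = "eda")
  b <- phys_ts(3.2 * v - 7, fs = 4, channel = "eda")
  expect_equal(znormalize(a)$values, znormalize(b)$values, tolerance = 1e-9)

  flat <- phys_ts(rep(2, 50), fs = 4, channel = "eda")
  expect_error(znormalize(flat), "zero variance.*eda")
})

test_that("block slicing is half-open and partitions exactly", {
  x <- phys_ts(rnorm(300 * 16), fs = 16, channel = "eda")
  s <- slice_block(x, list(onset = 40, offset = 70))
  expect_equal(length(s$values), 480)
  expect_equal(s$start_time, 40)

  expect_error(slice_block(x, list(onset = 400, offset = 500)), "intersect")

  # adjacent blocks partition the series with no shared or lost sample
  parts <- list(list(onset = 0, offset = 100), list(onset = 100, offset = 180),
                list(onset = 180, offset = 300))
  pieces <- lapply(parts, function(b) slice_block(x, b)$values)
  expect_identical(unlist(pieces), x$values)
})
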