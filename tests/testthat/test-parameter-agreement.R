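test_that("the boundary rule reproduces every printed a-priori boundary", {
  expect_equal(derive_boundary("scl", 0, 16)$boundary, 1.6)
  expect_equal(derive_boundary("scr_rate", 0, 25)$boundary, 2.5)
  expect_equal(derive_boundary("s_ampl", 0, 6)$boundary, 0.6)
  expect_equal(derive_boundary("hr", 60, 110)$boundary, 5)
  expect_equal(derive_boundary("sd_interval", 0, 0.56)$boundary, 0.06)
  expect_equal(derive_boundary("rmssd", 0, 0.71)$boundary, 0.07)

  expect_error(derive_boundary("x", 5, 5), "exceed")
  expect_error(derive_boundary("x", 0, 1, fraction = 1.2), "in \\(0, 1\\)")
})

test_that("Bland-Altman statistics match a hand computation", {
  # constant offset: sd 0, all within iff |c| <= boundary
  b <- derive_boundary("hr", 60, 110)
  x <- c(70, 75, 80, 85)
  p1 <- data.frame(participant = 1:4, rd = x, wd = x + 3)
  r1 <- bland_altman(p1, b)
  expect_equal(r1$mean_diff, 3)
  expect_equal(r1$sd_diff, 0)
  expect_equal(r1$pct_within_boundary, 100)
  p2 <- data.frame(participant = 1:4, rd = x, wd = x + 7)
  expect_equal(bland_altman(p2, b)$pct_within_boundary, 0)

  # four hand-built pairs with diffs {-1, 0, 1, 2}
  ph <- data.frame(participant = 1:4, rd = c(10, 11, 12, 13),
                   wd = c(9, 11, 13, 15))
  rh <- bland_altman(ph, b)
  expect_equal(rh$mean_diff, 0.5)
  sd_hand <- sqrt(((-1.5)^2 + (-0.5)^2 + 0.5^2 + 1.5^2) / 3)
  expect_equal(rh$sd_diff, sd_hand, tolerance = 1e-12)
  expect_equal(rh$loa_low, 0.5 - 1.96 * sd_hand, tolerance = 1e-12)
  expect_equal(rh$loa_high, 0.5 + 1.96 * sd_hand, tolerance = 1e-12)

  expect_error(bland_altman(ph[1:2, ], b), "at least 3")
})

test_that("missing sides are dropped and counted, and symmetry holds up to sign", {
  b <- derive_boundary("hr", 60, 110)
  set.seed(13)
  p <- data.frame(participant = 1:20, rd = rnorm(20, 75, 5),
                  wd = rnorm(20, 75, 5))
  p$wd[c(3, 7)] <- NA
  r <- skip_msgs(bland_altman(p, b))
  expect_equal(r$n, 18)
  expect_equal(r$n_dropped, 2)

  swapped <- data.frame(participant = p$participant, rd = p$wd, wd = p$rd)
  rs <- skip_msgs(bland_altman(swapped, b))
  expect_equal(rs$mean_diff, -r$mean_diff, tolerance = 1e-12)
  expect_equal(rs$loa_low, -r$loa_high, tolerance = 1e-12)
  expect_equal(rs$loa_high, -r$loa_low, tolerance = 1e-12)
})

test_that("about 95% of Gaussian differences fall within the limits of agreement", {
  set.seed(17)
  n <- 4000
  p <- data.frame(participant = seq_len(n), rd = rnorm(n, 75, 5))
  p$wd <- p$rd + rnorm(n, 0.5, 1)
  r <- bland_altman(p, derive_boundary("hr", 60, 110))
  expect_lt(abs(r$pct_within_loa - 95), 1)
})

test_that("log transform is applied for normality reporting only", {
  set.seed(19)
  rd <- rlnorm(30, 0, 0.6)
  p <- data.frame(participant = 1:30, rd = rd, wd = rd * rlnorm(30, 0.5, 0.5))
  b <- derive_boundary("s_ampl", 0, 6)
  r <- bland_altman(p, b, transform_policy = "log")
  expect_equal(r$transform, "log")
  # raw-scale statistics unchanged by the transform policy
  r0 <- bland_altman(p, b, transform_policy = "none")
  expect_equal(r$mean_diff, r0$mean_diff)
  expect_equal(r$loa_low, r0$loa_low)
})

test_that("the parameter verdict follows the boundary rule and flags bias", {
  b <- derive_boundary("hr", 60, 110)
  mk <- function(loa_low, loa_high, ci) {
    structure(list(parameter = "hr", mean_diff = mean(c(loa_low, loa_high)),
                   loa_low = loa_low, loa_high = loa_high,
                   mean_diff_ci = ci,
                   pairs = data.frame(mean_of_two = c(70, 80, 90),
                                      diff = c(0, 0.5, 1))),
              class = "bland_altman_result")
  }
  expect_equal(parameter_decision(mk(-2, 3, c(-1, 2)), b)$verdict, "valid")
  expect_equal(parameter_decision(mk(-6, 1, c(-4, 1)), b)$verdict, "invalid")

  d <- parameter_decision(mk(-3, -1, c(-2.1, -0.3)), b)
  expect_true(d$biased)
  expect_equal(d$bias_direction, "underestimation")

  # enlarging the boundary never flips valid -> invalid
  set.seed(23)
  for (i in 1:20) {
    lo <- runif(1, -8, 0); hi <- runif(1, 0, 8)
    small <- derive_boundary("hr", 60, 110, fraction = 0.10)
    big <- derive_boundary("hr", 60, 60 + runif(1, 60, 200))
    vs <- parameter_decision(mk(lo, hi, c(lo, hi)), small)$verdict
    vb <- parameter_decision(mk(lo, hi, c(lo, hi)), big)$verdict
    if (vs == "valid" && big$boundary >= small$boundary) {
      expect_equal(vb, "valid")
    }
  }
})
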