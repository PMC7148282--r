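mk_sum <- function(task, mean, se, n = 10, device = "rd") {
  data.frame(task = task, kind = "derived", device = device, mean = mean,
             se = se, n_available = n, stringsAsFactors = FALSE)
}

test_that("effects are detected by disjoint error bars, with an n >= 3 rule", {
  expect_true(detect_effect(mk_sum("b", 1.0, 0.1), mk_sum("t", 2.0, 0.2)))
  expect_false(detect_effect(mk_sum("b", 1.0, 0.5), mk_sum("t", 1.4, 0.3)))
  expect_true(is.na(detect_effect(mk_sum("b", 1.0, 0.1),
                                  mk_sum("t", 2.0, 0.2, n = 2))))
})

test_that("the reference effect is the RD baseline-to-task difference", {
  expect_equal(reference_effect(mk_sum("b", 1.0, 0.1), mk_sum("t", 2.5, 0.1)),
               1.5)
  expect_equal(reference_effect(mk_sum("b", 2.0, 0.1), mk_sum("t", 1.0, 0.1)),
               1.0)
  expect_equal(reference_effect(mk_sum("b", 1.0, 0.1), mk_sum("t", 1.0, 0.1)),
               0)
  expect_error(reference_effect(mk_sum("b", NA, 0.1), mk_sum("t", 1, 0.1)),
               "requires")
})

test_that("event comparisons measure the difference bar against zero and the band", {
  rd <- c(a = 1, b = 1.2, c = 0.9, d = 1.1)
  wd <- rd + c(0.05, -0.05, 0.1, -0.1)
  cm <- event_comparison("t", rd, wd, ref_effect = 1.5)
  expect_equal(cm$diff_mean, mean(wd - rd))
  expect_true(cm$crosses_zero)
  expect_true(cm$within_boundary)

  far <- event_comparison("t", rd, rd + 2, ref_effect = 1.5)
  expect_false(far$crosses_zero)
  expect_false(far$within_boundary)
})

test_that("the verdict rule chain matches the decision tree", {
  cm_ok <- event_comparison("t", c(a = 1, b = 1, c = 1),
                            c(a = 1.1, b = 0.9, c = 1.0), ref_effect = 1.5)
  expect_equal(event_decision(TRUE, TRUE, cm_ok)$verdict, "valid")

  expect_equal(event_decision(TRUE, FALSE, cm_ok)$verdict, "invalid")
  expect_equal(event_decision(FALSE, TRUE, cm_ok)$verdict, "inconclusive")
  expect_equal(event_decision(TRUE, NA, cm_ok)$verdict, "inconclusive_data")

  cm_off <- event_comparison("t", c(a = 1, b = 1, c = 1),
                             c(a = 1.2, b = 1.25, c = 1.22),
                             ref_effect = 1.5)
  expect_equal(event_decision(TRUE, TRUE, cm_off)$verdict, "invalid")
  expect_match(event_decision(TRUE, TRUE, cm_off)$reason, "cross zero")
})

test_that("identical devices give zero differences and valid verdicts wherever RD detects", {
  set.seed(29)
  for (i in 1:10) {
    v <- rnorm(8, 2, 0.5)
    names(v) <- letters[1:8]
    ref <- runif(1, 0.5, 2)
    cm <- event_comparison("t", v, v, ref_effect = ref)
    expect_equal(cm$diff_mean, 0)
    expect_true(cm$crosses_zero)
    expect_true(cm$within_boundary)
    expect_equal(event_decision(TRUE, TRUE, cm)$verdict, "valid")
  }
})

test_that("habituation decay is recovered exactly without noise", {
  a <- 0.8 * 0.96^(0:25)
  fit <- fit_habituation(a)
  expect_equal(fit$decay_rate, 0.04, tolerance = 1e-9)
  expect_equal(fit$n_stimuli, 26)

  flatfit <- fit_habituation(rep(0.5, 10))
  expect_equal(flatfit$decay_rate, 0, tolerance = 1e-12)

  expect_error(fit_habituation(c(1, 0.9)), "at least 3")
})

test_that("the habituation CI covers the true rate in noisy replicates", {
  set.seed(31)
  cover <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    y <- 0.8 * 0.96^(0:25) * rlnorm(26, 0, 0.15)
    ci <- fit_habituation(y)$ci
    if (min(ci) <= 0.04 && 0.04 <= max(ci)) cover <- cover + 1
  }
  expect_gte(cover / reps, 0.9)
})

test_that("task values extract block and beep-window parameters with gating", {
  sch <- event_schedule("P1", data.frame(
    label = c("base", "noise", "beep_01"),
    kind = c("baseline", "stressor", "beep"),
    onset = c(0, 60, 80), offset = c(60, 200, 80.2)))

  flat <- phys_ts(rep(2, 16 * 200), fs = 16, units = "uS", channel = "eda")
  none <- detect_scrs_ttp(flat)
  tv <- task_values("total_amplitude", sch, x = flat, events = none)
  expect_equal(tv$value[tv$task == "base"], 0)

  # one injected SCR of 0.5 uS inside the beep's 1-6 s response window
  # (bump centred at 84 so its trough-to-peak rise starts after onset+1)
  x <- bumpy_eda(onsets = 84, amps = 0.5, dur = 200)
  ev <- detect_scrs_ttp(smooth_eda(x))
  tv2 <- task_values("total_amplitude", sch, x = smooth_eda(x), events = ev)
  expect_equal(tv2$value[tv2$task == "beep_01"], 0.5, tolerance = 0.05)

  # gated-out CVA block is missing with a reason
  beats <- beat_train(0.8, 200)
  bad_sqi <- data.frame(start = seq(0, 190, by = 10),
                        end = seq(10, 200, by = 10), sqi = 10)
  tvc <- task_values("mean_hr", sch, beats = beats, sqi = bad_sqi)
  expect_true(all(is.na(tvc$value)))
  expect_match(tvc$reason[1], "gated out")

  expect_error(task_values("nope", sch), "unknown parameter")
})
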