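#' Per-task parameter values for one participant
#'
#' Extracts the event-level stress parameter per task: for block tasks the
#' parameter over the block, for `beep` stimuli the parameter over the
#' post-onset response window (default 1-6 s after the beep). The EDA stress
#' parameter is the SCR total amplitude; the cardiovascular one is mean
#' instantaneous heart rate, computed only where the block passes the
#' quality gate (gated-out tasks come back `NA` with a reason).
#'
#' @param parameter `"total_amplitude"` or `"mean_hr"`.
#' @param schedule an [event_schedule()].
#' @param window a [response_window()] for beep stimuli.
#' @param x smoothed EDA [phys_ts()] (for `total_amplitude`).
#' @param events `scr_events` from [detect_scrs_ttp()] (for
#'   `total_amplitude`).
#' @param beats a filtered [beat_series()] (for `mean_hr`).
#' @param sqi quality windows from [sqi_windows()] (for `mean_hr`).
#' @param gate quality-gate settings (see [gate_block()]).
#' @return data frame with columns `task`, `kind`, `value`, `reason`
#'   (`NA` value carries the exclusion reason).
#' @export
task_values <- function(parameter, schedule, window = response_window(),
                        x = NULL, events = NULL, beats = NULL, sqi = NULL,
                        gate = list(min_coverage = 0.5, sqi_long = 70,
                                    sqi_event = 80)) {
  if (!parameter %in% c("total_amplitude", "mean_hr")) {
    stop("unknown parameter: ", parameter)
  }
  blocks <- schedule$blocks
  rows <- lapply(seq_len(nrow(blocks)), function(i) {
    blk <- blocks[i, ]
    is_beep <- blk$kind == "beep"
    win <- if (is_beep) {
      list(onset = blk$onset + window$post_onset_start,
           offset = blk$onset + window$post_onset_end)
    } else list(onset = blk$onset, offset = blk$offset)
    if (parameter == "total_amplitude") {
      val <- tryCatch(
        eda_parameters(x, events, win)$total_amplitude,
        error = function(e) NA_real_)
      reason <- if (is.na(val)) "no signal in window" else NA_character_
    } else {
      g <- gate_block(sqi, win, gate, event = is_beep)
      if (!g$accepted) {
        val <- NA_real_
        reason <- sprintf("gated out (coverage %.2f < %.2f at SQI >= %g)",
                          g$coverage, gate$min_coverage, g$threshold)
      } else {
        val <- cva_parameters(beats, win)$mean_hr
        reason <- if (is.na(val)) "insufficient intervals" else NA_character_
      }
    }
    data.frame(task = blk$label, kind = blk$kind, value = val,
               reason = reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort task summaries
#'
#' Stacks per-participant [task_values()] tables into per-task cohort
#' summaries (mean, SE over the participants with a non-missing value).
#'
#' @param per_participant named list (participant id -> [task_values()]
#'   data frame).
#' @param device label, `"rd"` or `"wd"`.
#' @return data frame of class `task_summary` with columns `task`, `kind`,
#'   `device`, `mean`, `se`, `n_available`, plus attribute `values`
#'   (participant x task matrix).
#' @export
summarize_tasks <- function(per_participant, device = "rd") {
  stopifnot(length(per_participant) >= 1)
  tasks <- per_participant[[1]]$task
  kinds <- per_participant[[1]]$kind
  vals <- vapply(per_participant, function(d) {
    d$value[match(tasks, d$task)]
  }, numeric(length(tasks)))
  vals <- matrix(vals, nrow = length(tasks),
                 dimnames = list(tasks, names(per_participant)))
  out <- data.frame(
    task = tasks, kind = kinds, device = device,
    mean = apply(vals, 1, function(v) mean(v, na.rm = TRUE)),
    se = apply(vals, 1, function(v) {
      n <- sum(!is.na(v))
      if (n > 1) sd(v, na.rm = TRUE) / sqrt(n) else NA_real_
    }),
    n_available = apply(vals, 1, function(v) sum(!is.na(v))),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "values") <- t(vals)
  class(out) <- c("task_summary", "data.frame")
  out
}

summary_row <- function(summary, task) {
  r <- summary[summary$task == task, , drop = FALSE]
  if (nrow(r) != 1) stop("task not found in summary: ", task)
  r
}

#' Detect a stressor effect from error bars
#'
#' An effect is detected when the `mean +/- se` intervals of the baseline
#' and task summaries are disjoint — deliberately the informal error-bar
#' criterion rather than a t-test. Fewer than 3 available participants on
#' either side makes the comparison inconclusive (`NA`).
#'
#' @param baseline,task single rows of a [summarize_tasks()] table (same
#'   device and parameter).
#' @return `TRUE` (detected), `FALSE` (overlap: not detected) or `NA`
#'   (insufficient data).
#' @export
detect_effect <- function(baseline, task) {
  if (baseline$n_available < 3 || task$n_available < 3) return(NA)
  b_lo <- baseline$mean - baseline$se; b_hi <- baseline$mean + baseline$se
  t_lo <- task$mean - task$se; t_hi <- task$mean + task$se
  (t_lo > b_hi) || (t_hi < b_lo)
}

#' Reference effect of a task
#'
#' The event-level acceptance band is the effect the reference device itself
#' measures: the absolute difference between the RD task mean and the RD
#' baseline mean.
#'
#' @param baseline_rd,task_rd single RD rows of a [summarize_tasks()] table.
#' @return non-negative effect size in the parameter's units.
#' @export
reference_effect <- function(baseline_rd, task_rd) {
  if (is.na(baseline_rd$mean) || is.na(task_rd$mean)) {
    stop("reference effect requires RD baseline and task means")
  }
  abs(task_rd$mean - baseline_rd$mean)
}

#' Device difference for one task
#'
#' Per-participant wearable-minus-reference differences for a task, their
#' mean and SE, whether the error bar crosses zero, and whether it stays
#' inside the reference-effect band.
#'
#' @param task task label.
#' @param rd_values,wd_values named numeric vectors
#'   (participant -> task value) for the two devices.
#' @param ref_effect the [reference_effect()] for this task.
#' @return list of class `event_comparison`.
#' @export
event_comparison <- function(task, rd_values, wd_values, ref_effect) {
  common <- intersect(names(rd_values), names(wd_values))
  d <- wd_values[common] - rd_values[common]
  d <- d[!is.na(d)]
  n <- length(d)
  m <- if (n > 0) mean(d) else NA_real_
  se <- if (n > 1) sd(d) / sqrt(n) else NA_real_
  crosses <- if (n > 1) (m - se) <= 0 && 0 <= (m + se) else NA
  within <- if (n > 1 && !is.na(ref_effect)) {
    (m - se) >= -ref_effect && (m + se) <= ref_effect
  } else NA
  structure(list(task = task, diffs = d, diff_mean = m, diff_se = se,
                 ref_effect = ref_effect, crosses_zero = crosses,
                 within_boundary = within, n = n),
            class = "event_comparison")
}

#' Event-level verdict for one task
#'
#' Ordered decision rules: (1) if the RD shows no effect the task is
#' `inconclusive` — no further inference about the wearable is possible;
#' (2) if the RD shows the effect but the wearable does not, `invalid`;
#' (3) if both show it, `invalid` when the difference bar misses zero or
#' exceeds the reference-effect band, else `valid`; (4) insufficient
#' wearable data gives `inconclusive_data`.
#'
#' @param rd_effect,wd_effect [detect_effect()] results for the task
#'   (`TRUE`/`FALSE`/`NA`).
#' @param comparison an [event_comparison()] for the task.
#' @param wd_missing_frac fraction of the cohort whose wearable value for
#'   this task is missing (gated out or unavailable).
#' @param max_missing missingness above which the comparison is deemed
#'   data-insufficient even if a few participants survive (default 0.5:
#'   when most of the cohort is gated out, the surviving error bars are not
#'   informative).
#' @return list of class `event_verdict`: `task`, `verdict`, `reason`.
#' @export
event_decision <- function(rd_effect, wd_effect, comparison,
                           wd_missing_frac = 0, max_missing = 0.5) {
  task <- comparison$task
  res <- if (is.na(rd_effect)) {
    list("inconclusive_data", "insufficient reference-device data")
  } else if (!rd_effect) {
    list("inconclusive",
         "reference device shows no effect; no further inferences")
  } else if (is.na(wd_effect) || wd_missing_frac > max_missing) {
    list("inconclusive_data", sprintf(
      "insufficient wearable data for this task (%.0f%% missing)",
      100 * wd_missing_frac))
  } else if (!wd_effect) {
    list("invalid",
         "wearable does not detect the stressor the reference device detects")
  } else if (isTRUE(comparison$crosses_zero) &&
             isTRUE(comparison$within_boundary)) {
    list("valid",
         "both devices detect the effect; difference bar crosses zero and stays within the reference-effect band")
  } else if (!isTRUE(comparison$crosses_zero)) {
    list("invalid", "difference bar does not cross zero")
  } else {
    list("invalid", "difference bar exceeds the reference-effect band")
  }
  structure(list(task = task, verdict = res[[1]], reason = res[[2]]),
            class = "event_verdict")
}

#' Fit a habituation decay over repeated stimuli
#'
#' Ordinary least squares of log mean response amplitude on stimulus index
#' (0-based). For amplitudes following `a * (1 - rate)^i` the slope is
#' `log(1 - rate)`, so the decay rate is recovered as `1 - exp(slope)`;
#' its CI comes from the slope's standard error. Zero means are floored
#' before the log.
#'
#' @param beep_means ordered per-stimulus cohort mean amplitudes.
#' @param level confidence level (default 0.95).
#' @param floor replacement for non-positive means before `log`.
#' @return list of class `habituation_fit`: `decay_rate`, `intercept`,
#'   `n_stimuli`, `ci`.
#' @export
fit_habituation <- function(beep_means, level = 0.95, floor = 1e-6) {
  y <- as.numeric(beep_means)
  y[!is.na(y) & y <= 0] <- floor
  ok <- !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 usable stimulus means")
  i <- seq_along(y) - 1
  fit <- lm(log(y[ok]) ~ i[ok])
  slope <- coef(fit)[2]
  ci_slope <- suppressWarnings(confint(fit, level = level)[2, ])
  structure(list(
    decay_rate = unname(1 - exp(slope)),
    intercept = unname(exp(coef(fit)[1])),
    n_stimuli = sum(ok),
    ci = unname(rev(1 - exp(ci_slope)))
  ), class = "habituation_fit")
}

#' @export
print.habituation_fit <- function(x, ...) {
  cat(sprintf("<habituation_fit> decay %.2f%% per stimulus (CI %.2f%% to %.2f%%) over %d stimuli\n",
              100 * x$decay_rate, 100 * x$ci[1], 100 * x$ci[2], x$n_stimuli))
  invisible(x)
}
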