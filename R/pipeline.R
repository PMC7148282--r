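# end-to-end protocol driver: preprocessing, the three levels, verdict

preprocess_eda <- function(rec, config) {
  if (!("eda" %in% names(rec$rd)) || !("eda" %in% names(rec$wd))) {
    return(NULL)
  }
  rd16 <- resample_to(rec$rd$eda, config$eda_fs)
  wd16 <- resample_to(rec$wd$eda, config$eda_fs)
  rd_s <- smooth_eda(rd16, cutoff = config$eda_smooth_cutoff)
  wd_s <- smooth_eda(wd16, cutoff = config$eda_smooth_cutoff)
  rd_ev <- detect_scrs_ttp(rd_s, threshold = config$scr_threshold,
                           min_rise = config$scr_min_rise,
                           max_rise = config$scr_max_rise)
  wd_ev <- detect_scrs_ttp(wd_s, threshold = config$scr_threshold,
                           min_rise = config$scr_min_rise,
                           max_rise = config$scr_max_rise)
  nr_rd <- flag_nonresponder(rd_s, rd_ev)
  nr_wd <- flag_nonresponder(wd_s, wd_ev)
  list(rd16 = rd16, wd16 = wd16, rd_smooth = rd_s, wd_smooth = wd_s,
       rd_events = rd_ev, wd_events = wd_ev,
       nonresponder = nr_rd$nonresponder || nr_wd$nonresponder,
       nonresponder_reason = if (nr_rd$nonresponder) {
         paste("rd:", nr_rd$reason)
       } else if (nr_wd$nonresponder) paste("wd:", nr_wd$reason) else NA)
}

preprocess_cva_side <- function(rec, side, config) {
  ts <- rec[[side]]
  bs <- rec[[paste0(side, "_beats")]]
  wave <- NULL
  if (is.null(bs)) {
    ch <- intersect(c("ecg", "ppg"), names(ts))
    if (length(ch) == 0) return(NULL)
    wave <- resample_to(ts[[ch[1]]], config$cardiac_fs)
    wave <- bandpass_cardiac(wave)
    bs <- detect_beats(wave)
  }
  bs <- suppressMessages(filter_intervals(bs, config$interval_bounds))
  span <- c(min(rec$schedule$blocks$onset), max(rec$schedule$blocks$offset))
  sqi <- sqi_windows(wave, bs, window_len = config$sqi_window_len,
                     span = span)
  list(beats = bs, sqi = sqi)
}

# evaluation windows with comparable lengths: the task baseline is the
# trailing sub-window of the first baseline block matched to the stressor
# length; the beep baseline is a response-window-length slice just before
# the noise block
eval_blocks <- function(schedule, config) {
  blocks <- schedule$blocks
  base <- blocks[blocks$kind == "baseline", ][1, ]
  beeps <- blocks[blocks$kind == "beep", , drop = FALSE]
  noise <- blocks[blocks$kind == "stressor" & blocks$label == "noise", ]
  tasks <- blocks[blocks$kind %in% c("anticipation", "stressor") &
                    blocks$label != "noise", , drop = FALSE]
  task_len <- if (nrow(tasks) > 0) min(tasks$offset - tasks$onset) else 30
  out <- data.frame(
    label = "task_baseline", kind = "baseline",
    onset = base$offset - task_len, offset = base$offset,
    stringsAsFactors = FALSE)
  if (nrow(tasks) > 0) {
    out <- rbind(out, tasks[, c("label", "kind", "onset", "offset")])
  }
  rw <- config$response_window
  if (nrow(beeps) > 0 && nrow(noise) == 1) {
    blen <- rw[2] - rw[1]
    out <- rbind(out, data.frame(
      label = "beep_baseline", kind = "baseline",
      onset = noise$onset - blen - 1, offset = noise$onset - 1))
    out <- rbind(out, beeps[, c("label", "kind", "onset", "offset")])
  }
  rownames(out) <- NULL
  out
}

event_channel_analysis <- function(values_by_pid, device_pair, config) {
  rw <- response_window(config$response_window[1], config$response_window[2])
  rd_sum <- summarize_tasks(values_by_pid$rd, device = "rd")
  wd_sum <- summarize_tasks(values_by_pid$wd, device = "wd")
  if (config$se_multiplier != 1) {
    rd_sum$se <- rd_sum$se * config$se_multiplier
    wd_sum$se <- wd_sum$se * config$se_multiplier
  }
  rd_vals <- attr(rd_sum, "values"); wd_vals <- attr(wd_sum, "values")

  # collapse the individual beeps into an early-beep task (mean of the
  # first three stimuli per participant), which carries the noise verdict
  beep_tasks <- grep("^beep_[0-9]+$", rd_sum$task, value = TRUE)
  task_list <- list()
  for (tk in setdiff(rd_sum$task, c("task_baseline", "beep_baseline",
                                    beep_tasks))) {
    task_list[[tk]] <- list(task = tk, baseline = "task_baseline",
                            rd = rd_vals[, tk], wd = wd_vals[, tk])
  }
  if (length(beep_tasks) >= 3) {
    early <- beep_tasks[1:3]
    task_list[["noise_beeps"]] <- list(
      task = "noise_beeps", baseline = "beep_baseline",
      rd = rowMeans(rd_vals[, early, drop = FALSE], na.rm = FALSE),
      wd = rowMeans(wd_vals[, early, drop = FALSE], na.rm = FALSE))
  }

  mk_row <- function(vals, task, device) {
    v <- vals
    n <- sum(!is.na(v))
    data.frame(task = task, kind = "derived", device = device,
               mean = mean(v, na.rm = TRUE),
               se = if (n > 1) sd(v, na.rm = TRUE) / sqrt(n) *
                 config$se_multiplier else NA_real_,
               n_available = n, stringsAsFactors = FALSE)
  }

  comparisons <- list(); verdicts <- list()
  for (tk in names(task_list)) {
    tl <- task_list[[tk]]
    rd_base <- summary_row(rd_sum, tl$baseline)
    wd_base <- summary_row(wd_sum, tl$baseline)
    rd_task <- if (tl$task %in% rd_sum$task) summary_row(rd_sum, tl$task)
      else mk_row(tl$rd, tl$task, "rd")
    wd_task <- if (tl$task %in% wd_sum$task) summary_row(wd_sum, tl$task)
      else mk_row(tl$wd, tl$task, "wd")
    rd_eff <- detect_effect(rd_base, rd_task)
    wd_eff <- detect_effect(wd_base, wd_task)
    ref <- if (!is.na(rd_base$mean) && !is.na(rd_task$mean)) {
      reference_effect(rd_base, rd_task)
    } else NA_real_
    cmp <- event_comparison(tl$task, tl$rd, tl$wd, ref)
    comparisons[[tk]] <- cmp
    wd_miss <- mean(is.na(tl$wd))
    verdicts[[tk]] <- event_decision(rd_eff, wd_eff, cmp,
                                     wd_missing_frac = wd_miss)
  }

  habituation <- NULL
  if (length(beep_tasks) >= 3) {
    # baseline-correct the per-beep means: the matched-length baseline
    # window estimates the spontaneous-response floor inside each
    # post-beep window, which would otherwise flatten the decay
    rd_beep_means <- rd_sum$mean[match(beep_tasks, rd_sum$task)]
    floor_mean <- rd_sum$mean[rd_sum$task == "beep_baseline"]
    if (length(floor_mean) == 1 && !is.na(floor_mean)) {
      rd_beep_means <- rd_beep_means - floor_mean
    }
    habituation <- tryCatch(fit_habituation(rd_beep_means),
                            error = function(e) NULL)
  }
  list(rd_summary = rd_sum, wd_summary = wd_sum, comparisons = comparisons,
       verdicts = verdicts, habituation = habituation)
}

#' Run the full validity-assessment protocol on a cohort
#'
#' Preprocesses every recording (resampling, smoothing, SCR and beat
#' pipelines, nonresponder exclusion), then computes the requested levels:
#' signal (EDA cross-correlation; not applicable when the two devices use
#' different cardiac modalities), parameter (Bland-Altman per parameter
#' against the a-priori boundaries) and event (per-task effect detection
#' and difference analysis for the sing-a-song stressor and the noise
#' task), and assembles the decision-tree verdict. Every exclusion is
#' logged.
#'
#' @param recordings named list of [paired_recording()] (e.g. from
#'   [simulate_cohort()] or [read_recording()]).
#' @param config a [default_config()] list.
#' @param levels subset of `c("signal", "parameter", "event")`.
#' @param channels subset of `c("eda", "cva")`.
#' @return list of class `protocol_results` with elements `signal`,
#'   `parameter`, `event`, `verdict`, `exclusions`, `config`.
#' @export
run_protocol <- function(recordings, config = default_config(),
                         levels = c("signal", "parameter", "event"),
                         channels = c("eda", "cva")) {
  stopifnot(length(recordings) >= 1)
  exclusions <- character(0)
  gate <- config_gate(config)

  eda_pp <- list(); cva_rd <- list(); cva_wd <- list()
  for (pid in names(recordings)) {
    rec <- recordings[[pid]]
    if ("eda" %in% channels) {
      pp <- preprocess_eda(rec, config)
      if (!is.null(pp)) {
        if (pp$nonresponder) {
          exclusions <- c(exclusions, sprintf(
            "%s: nonresponder excluded (%s)", pid, pp$nonresponder_reason))
        } else eda_pp[[pid]] <- pp
      }
    }
    if ("cva" %in% channels) {
      r <- preprocess_cva_side(rec, "rd", config)
      w <- preprocess_cva_side(rec, "wd", config)
      if (!is.null(r)) cva_rd[[pid]] <- r
      if (!is.null(w)) cva_wd[[pid]] <- w
      if (!is.null(r)) {
        nrm <- attr(r$beats, "n_removed")
        if (!is.null(nrm) && nrm > 0) {
          exclusions <- c(exclusions, sprintf(
            "%s rd: %d implausible intervals deleted", pid, nrm))
        }
      }
    }
  }

  signal <- NULL
  if ("signal" %in% levels) {
    if (length(eda_pp) > 0) {
      cc <- lapply(names(eda_pp), function(pid) {
        pp <- eda_pp[[pid]]
        r <- cross_correlation_lags(znormalize(detrend_linear(pp$rd16)),
                                    znormalize(detrend_linear(pp$wd16)),
                                    max_lag = config$max_lag)
        r$participant_id <- pid
        r
      })
      names(cc) <- names(eda_pp)
      signal <- cohort_signal_decision(cc, threshold = config$corr_threshold)
      names(signal$best_r) <- names(eda_pp)
    } else if ("cva" %in% channels) {
      signal <- "not_applicable"
    }
  }

  parameter <- NULL
  if ("parameter" %in% levels) {
    boundaries <- default_boundaries()
    pair_tab <- function(get_rd, get_wd, pids) {
      data.frame(participant = pids,
                 rd = vapply(pids, get_rd, numeric(1)),
                 wd = vapply(pids, get_wd, numeric(1)),
                 stringsAsFactors = FALSE)
    }
    ba <- list(); dec <- list()
    if (length(eda_pp) >= 3) {
      pids <- names(eda_pp)
      ep <- lapply(eda_pp, function(pp) list(
        rd = eda_parameters(pp$rd_smooth, pp$rd_events),
        wd = eda_parameters(pp$wd_smooth, pp$wd_events)))
      for (prm in c("scl", "scr_rate", "s_ampl")) {
        field <- c(scl = "scl_mean", scr_rate = "scr_per_min",
                   s_ampl = "total_amplitude")[[prm]]
        tab <- pair_tab(function(p) ep[[p]]$rd[[field]],
                        function(p) ep[[p]]$wd[[field]], pids)
        ba[[prm]] <- bland_altman(tab, boundaries[[prm]])
        dec[[prm]] <- parameter_decision(ba[[prm]], boundaries[[prm]])
      }
    }
    if (length(cva_rd) >= 3 && length(cva_wd) >= 3) {
      pids <- intersect(names(cva_rd), names(cva_wd))
      whole <- function(side, pid) {
        s <- side[[pid]]
        blk <- list(onset = min(s$sqi$start), offset = max(s$sqi$end))
        g <- gate_block(s$sqi, blk, gate, event = FALSE)
        if (!g$accepted) return(structure(list(mean_hr = NA_real_,
                                               sd_interval = NA_real_,
                                               rmssd = NA_real_),
                                          class = "cva_params"))
        cva_parameters(s$beats)
      }
      prd <- lapply(pids, function(p) whole(cva_rd, p))
      pwd <- lapply(pids, function(p) whole(cva_wd, p))
      names(prd) <- names(pwd) <- pids
      for (prm in c("hr", "sd_interval", "rmssd")) {
        field <- c(hr = "mean_hr", sd_interval = "sd_interval",
                   rmssd = "rmssd")[[prm]]
        tab <- pair_tab(function(p) prd[[p]][[field]] %||% NA_real_,
                        function(p) pwd[[p]][[field]] %||% NA_real_, pids)
        res <- tryCatch(bland_altman(tab, boundaries[[prm]]),
                        error = function(e) NULL)
        if (!is.null(res)) {
          ba[[prm]] <- res
          dec[[prm]] <- parameter_decision(res, boundaries[[prm]])
          if (res$n_dropped > 0) {
            exclusions <- c(exclusions, sprintf(
              "parameter %s: %d pair(s) dropped for missing data",
              prm, res$n_dropped))
          }
        } else {
          exclusions <- c(exclusions, sprintf(
            "parameter %s: fewer than 3 complete pairs; not computed", prm))
        }
      }
    }
    if (length(ba) > 0) {
      parameter <- list(bland_altman = ba, decisions = dec,
                        boundaries = boundaries)
    }
  }

  event <- NULL
  if ("event" %in% levels) {
    event <- list()
    rw <- response_window(config$response_window[1],
                          config$response_window[2])
    if (length(eda_pp) >= 1) {
      sch1 <- recordings[[1]]$schedule
      eb <- eval_blocks(sch1, config)
      vals <- list(rd = list(), wd = list())
      for (pid in names(eda_pp)) {
        pp <- eda_pp[[pid]]
        vals$rd[[pid]] <- task_values("total_amplitude",
                                      list(blocks = eb), rw,
                                      x = pp$rd_smooth, events = pp$rd_events)
        vals$wd[[pid]] <- task_values("total_amplitude",
                                      list(blocks = eb), rw,
                                      x = pp$wd_smooth, events = pp$wd_events)
      }
      event$eda <- event_channel_analysis(vals, "eda", config)
    }
    if (length(cva_rd) >= 1 && length(cva_wd) >= 1) {
      pids <- intersect(names(cva_rd), names(cva_wd))
      sch1 <- recordings[[pids[1]]]$schedule
      eb <- eval_blocks(sch1, config)
      vals <- list(rd = list(), wd = list())
      for (pid in pids) {
        vals$rd[[pid]] <- task_values("mean_hr", list(blocks = eb), rw,
                                      beats = cva_rd[[pid]]$beats,
                                      sqi = cva_rd[[pid]]$sqi, gate = gate)
        vals$wd[[pid]] <- task_values("mean_hr", list(blocks = eb), rw,
                                      beats = cva_wd[[pid]]$beats,
                                      sqi = cva_wd[[pid]]$sqi, gate = gate)
      }
      event$cva <- event_channel_analysis(vals, "cva", config)
      miss <- vapply(vals$wd, function(d) mean(is.na(d$value)), numeric(1))
      exclusions <- c(exclusions, sprintf(
        "cva events: %.0f%% of wearable task values missing after gating",
        100 * mean(miss)))
    }
    if (length(event) == 0) event <- NULL
  }

  events_flat <- NULL
  if (!is.null(event)) {
    events_flat <- list()
    for (ch in names(event)) {
      for (tk in names(event[[ch]]$verdicts)) {
        events_flat[[paste(ch, tk, sep = ":")]] <- event[[ch]]$verdicts[[tk]]
      }
    }
  }
  verdict <- assemble_verdict(
    signal = signal,
    parameters = if (!is.null(parameter)) parameter$decisions else NULL,
    events = events_flat, config = config)

  structure(list(signal = if (inherits(signal, "signal_verdict")) signal
                 else NULL,
                 parameter = parameter, event = event, verdict = verdict,
                 exclusions = exclusions, config = config),
            class = "protocol_results")
}
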