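#' Assemble the three levels into an overall verdict
#'
#' Implements the protocol's decision tree: a signal-level pass
#' short-circuits with implied validity of the lower levels (agreement on
#' raw signals guarantees agreement on anything derived from them);
#' otherwise the parameter- and event-level verdicts are both reported —
#' the event level is always worth assessing because per-person aggregation
#' can hide compensating biases. A signal level of `"not_applicable"`
#' (e.g. ECG vs PPG, which are different waveforms by construction) is
#' recorded with its reason and the lower levels carry the verdict.
#'
#' @param signal a [cohort_signal_decision()] result, the string
#'   `"not_applicable"`, or `NULL` when not computed.
#' @param parameters named list of [parameter_decision()] results (may be
#'   `NULL`).
#' @param events named list of [event_decision()] results (may be `NULL`).
#' @param config the configuration list used (hashed for provenance).
#' @return list of class `protocol_verdict`: `signal` (`"pass"`, `"fail"`,
#'   `"not_applicable"` or `"not_run"`), `parameter` and `event` maps,
#'   `notes` (machine-readable reasons), `config_hash`.
#' @export
assemble_verdict <- function(signal = NULL, parameters = NULL, events = NULL,
                             config = default_config()) {
  if (is.null(signal) && is.null(parameters) && is.null(events)) {
    stop("no level was computed")
  }
  notes <- character(0)
  sig_state <- "not_run"
  if (inherits(signal, "signal_verdict")) {
    sig_state <- if (signal$pass) "pass" else "fail"
    notes <- c(notes, sprintf(
      "signal level %s: best cross-correlations in [%.2f, %.2f] vs threshold %.2f",
      sig_state, min(signal$best_r), max(signal$best_r), signal$threshold))
  } else if (identical(signal, "not_applicable")) {
    sig_state <- "not_applicable"
    notes <- c(notes,
               "signal level not applicable: reference and wearable use different signal modalities (e.g. ECG vs PPG)")
  }
  param_map <- list()
  if (!is.null(parameters)) {
    for (nm in names(parameters)) {
      pv <- parameters[[nm]]
      param_map[[nm]] <- list(verdict = pv$verdict, biased = pv$biased,
                              reason = pv$reason)
      notes <- c(notes, sprintf("parameter %s: %s", nm, pv$reason))
    }
  }
  event_map <- list()
  if (!is.null(events)) {
    for (nm in names(events)) {
      ev <- events[[nm]]
      event_map[[nm]] <- list(verdict = ev$verdict, reason = ev$reason)
      notes <- c(notes, sprintf("event %s: %s - %s", nm, ev$verdict, ev$reason))
    }
  }
  if (sig_state == "pass") {
    notes <- c(notes,
               "signal level passed: parameter and event levels are implied valid")
    if (length(param_map) == 0) param_map <- list(implied = list(
      verdict = "valid", biased = FALSE, reason = "implied by signal-level pass"))
    if (length(event_map) == 0) event_map <- list(implied = list(
      verdict = "valid", reason = "implied by signal-level pass"))
  }
  level_state <- function(m, key = "verdict") {
    if (length(m) == 0) return("not_run")
    v <- vapply(m, function(e) e[[key]], character(1))
    if (all(v == "valid")) "valid"
    else if (any(v == "invalid")) "invalid"
    else "inconclusive"
  }
  overall <- list(
    signal = sig_state,
    parameter = if (sig_state == "pass") "valid_implied"
                else level_state(param_map),
    event = if (sig_state == "pass") "valid_implied"
            else level_state(event_map))
  structure(list(signal = sig_state, parameter = param_map,
                 event = event_map, overall = overall, notes = notes,
                 config_hash = config_hash(config)),
            class = "protocol_verdict")
}

#' @export
print.protocol_verdict <- function(x, ...) {
  cat("<protocol_verdict>\n")
  cat("  signal:", x$signal, "\n")
  if (length(x$parameter)) {
    cat("  parameter:\n")
    for (nm in names(x$parameter)) {
      p <- x$parameter[[nm]]
      cat(sprintf("    %-12s %s%s\n", nm, p$verdict,
                  if (isTRUE(p$biased)) sprintf(" (biased: %s)",
                                                x$parameter[[nm]]$reason) else ""))
    }
  }
  if (length(x$event)) {
    cat("  event:\n")
    for (nm in names(x$event)) {
      cat(sprintf("    %-12s %s\n", nm, x$event[[nm]]$verdict))
    }
  }
  cat("  config:", x$config_hash, "\n")
  invisible(x)
}

#' Render the protocol report
#'
#' Writes a machine-readable JSON verdict, a human-readable text summary,
#' the derived tables as CSV, and the protocol figures. Deterministic for
#' identical inputs and configuration.
#'
#' @param results a [run_protocol()] result.
#' @param out_dir output directory (created if needed).
#' @param figures write figure files? (default TRUE; requires a functional
#'   graphics device).
#' @return named list of written paths, invisibly.
#' @export
render_report <- function(results, out_dir, figures = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  paths$verdict_json <- file.path(out_dir, "verdict.json")
  jsonlite::write_json(unclass(results$verdict), paths$verdict_json,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  write_tab <- function(d, name) {
    p <- file.path(out_dir, name)
    write.csv(d, p, row.names = FALSE)
    p
  }
  if (!is.null(results$signal)) {
    sv <- results$signal
    tab <- data.frame(participant = names(sv$best_r) %||%
                        seq_along(sv$best_r),
                      best_lag = sv$best_lag, best_r = sv$best_r)
    rtab <- t(vapply(sv$per_participant, function(r) r$r_by_lag,
                     numeric(length(sv$per_participant[[1]]$lags))))
    colnames(rtab) <- paste0("lag_", sv$per_participant[[1]]$lags)
    paths$signal_table <- write_tab(cbind(tab, rtab), "signal_crosscorr.csv")
  }
  if (!is.null(results$parameter)) {
    for (nm in names(results$parameter$bland_altman)) {
      ba <- results$parameter$bland_altman[[nm]]
      paths[[paste0("pairs_", nm)]] <-
        write_tab(ba$pairs, sprintf("parameter_pairs_%s.csv", nm))
    }
    summ <- do.call(rbind, lapply(names(results$parameter$bland_altman),
                                  function(nm) {
      ba <- results$parameter$bland_altman[[nm]]
      pd <- results$parameter$decisions[[nm]]
      data.frame(parameter = nm, n = ba$n, mean_diff = ba$mean_diff,
                 sd_diff = ba$sd_diff, loa_low = ba$loa_low,
                 loa_high = ba$loa_high, boundary = ba$boundary,
                 pct_within_boundary = ba$pct_within_boundary,
                 pct_within_loa = ba$pct_within_loa,
                 transform = ba$transform, verdict = pd$verdict,
                 biased = pd$biased)
    }))
    paths$parameter_summary <- write_tab(summ, "parameter_summary.csv")
  }
  if (!is.null(results$event)) {
    for (nm in names(results$event)) {
      ev <- results$event[[nm]]
      paths[[paste0("event_summary_", nm)]] <-
        write_tab(rbind(ev$rd_summary, ev$wd_summary),
                  sprintf("event_summaries_%s.csv", nm))
      comp <- do.call(rbind, lapply(ev$comparisons, function(cm) {
        data.frame(task = cm$task, diff_mean = cm$diff_mean,
                   diff_se = cm$diff_se, ref_effect = cm$ref_effect,
                   crosses_zero = cm$crosses_zero,
                   within_boundary = cm$within_boundary, n = cm$n)
      }))
      if (!is.null(comp)) {
        paths[[paste0("event_comparisons_", nm)]] <-
          write_tab(comp, sprintf("event_comparisons_%s.csv", nm))
      }
      verd <- do.call(rbind, lapply(ev$verdicts, function(v) {
        data.frame(task = v$task, verdict = v$verdict, reason = v$reason)
      }))
      paths[[paste0("event_verdicts_", nm)]] <-
        write_tab(verd, sprintf("event_verdicts_%s.csv", nm))
    }
  }

  txt <- file.path(out_dir, "report.txt")
  con <- file(txt, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("Validity assessment report",
               strrep("=", 26), "",
               utils::capture.output(print(results$verdict)), "",
               "Exclusion log:", results$exclusions %||% "(none)"), con)
  paths$report_txt <- txt

  if (figures) {
    paths <- c(paths, render_figures(results, out_dir))
  }
  invisible(paths)
}
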