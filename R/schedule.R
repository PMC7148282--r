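#' Experiment event schedule
#'
#' Ordered blocks of one participant's session: baselines, anticipation,
#' stressor and recovery periods, plus short `beep` stimulus markers that may
#' sit inside a stressor block (the noise task). Intervals are half-open
#' `[onset, offset)` seconds from recording start.
#'
#' @param participant_id participant identifier.
#' @param blocks data frame with columns `label`, `kind` (one of `baseline`,
#'   `anticipation`, `stressor`, `recovery`, `beep`), `onset`, `offset`
#'   (seconds).
#' @return an object of class `event_schedule`.
#' @export
event_schedule <- function(participant_id, blocks) {
  need <- c("label", "kind", "onset", "offset")
  if (!all(need %in% names(blocks))) {
    stop("blocks must have columns label, kind, onset, offset")
  }
  kinds <- c("baseline", "anticipation", "stressor", "recovery", "beep")
  if (!all(blocks$kind %in% kinds)) {
    stop("unknown block kind: ", paste(setdiff(blocks$kind, kinds), collapse = ", "))
  }
  if (any(!(blocks$onset < blocks$offset))) {
    bad <- which(!(blocks$onset < blocks$offset))[1]
    stop(sprintf("block '%s': onset must be < offset", blocks$label[bad]))
  }
  blocks <- blocks[order(blocks$onset), , drop = FALSE]
  rownames(blocks) <- NULL
  # non-beep blocks must not overlap; beeps may only nest inside a stressor
  main <- blocks[blocks$kind != "beep", , drop = FALSE]
  if (nrow(main) > 1) {
    for (i in seq_len(nrow(main) - 1)) {
      if (main$offset[i] > main$onset[i + 1] + 1e-9) {
        stop(sprintf("blocks '%s' and '%s' overlap",
                     main$label[i], main$label[i + 1]))
      }
    }
  }
  beeps <- blocks[blocks$kind == "beep", , drop = FALSE]
  if (nrow(beeps) > 0) {
    inside <- vapply(seq_len(nrow(beeps)), function(i) {
      any(main$kind == "stressor" &
            main$onset <= beeps$onset[i] + 1e-9 &
            main$offset >= beeps$offset[i] - 1e-9)
    }, logical(1))
    if (!all(inside)) {
      stop("beep markers must lie inside a stressor block")
    }
  }
  structure(list(participant_id = participant_id, blocks = blocks),
            class = "event_schedule")
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("<event_schedule> participant %s: %d blocks (%d beeps), span [%.0f, %.0f) s\n",
              x$participant_id, nrow(x$blocks),
              sum(x$blocks$kind == "beep"),
              min(x$blocks$onset), max(x$blocks$offset)))
  invisible(x)
}

#' Post-stimulus response window
#'
#' The window, relative to a stimulus onset, in which a phasic response is
#' scored. The default 1-6 s after the beep matches the expected latency of
#' event-related skin conductance responses.
#'
#' @param post_onset_start,post_onset_end window bounds in seconds after
#'   stimulus onset; `0 <= start < end`.
#' @return an object of class `response_window`.
#' @export
response_window <- function(post_onset_start = 1, post_onset_end = 6) {
  if (!(post_onset_start >= 0 && post_onset_start < post_onset_end)) {
    stop("need 0 <= post_onset_start < post_onset_end")
  }
  structure(list(post_onset_start = post_onset_start,
                 post_onset_end = post_onset_end),
            class = "response_window")
}

#' Read an event schedule from CSV
#'
#' Expects columns `participant`, `label`, `kind`, `onset_s`, `offset_s`.
#' @param path file path.
#' @return an [event_schedule()].
#' @export
read_schedule_csv <- function(path) {
  if (!file.exists(path)) stop("schedule file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "label", "kind", "onset_s", "offset_s")
  if (!all(need %in% names(d))) {
    stop("schedule must have columns ", paste(need, collapse = ", "))
  }
  pid <- unique(d$participant)
  if (length(pid) != 1) stop("schedule file must describe one participant")
  event_schedule(pid, data.frame(label = d$label, kind = d$kind,
                                 onset = d$onset_s, offset = d$offset_s,
                                 stringsAsFactors = FALSE))
}

#' Write an event schedule to CSV
#' @param schedule an [event_schedule()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  d <- data.frame(participant = schedule$participant_id,
                  label = schedule$blocks$label,
                  kind = schedule$blocks$kind,
                  onset_s = schedule$blocks$onset,
                  offset_s = schedule$blocks$offset)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
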