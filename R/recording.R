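#' Paired reference-device / wearable recording
#'
#' One participant's synchronized recordings: reference-device (`rd`) and
#' wearable (`wd`) channel maps, optional pre-detected beat series on either
#' side, and the session's event schedule. Both sides are assumed to share
#' one clock (seconds from recording start); the package does not attempt to
#' re-synchronize independent clocks.
#'
#' @param participant_id participant identifier.
#' @param rd,wd named lists of [phys_ts()] keyed by channel
#'   (`eda`, `ecg`, `ppg`); may be empty.
#' @param schedule an [event_schedule()].
#' @param rd_beats,wd_beats optional [beat_series()] supplied instead of (or
#'   in addition to) raw cardiac waveforms.
#' @return an object of class `paired_recording`.
#' @export
paired_recording <- function(participant_id, rd = list(), wd = list(),
                             schedule, rd_beats = NULL, wd_beats = NULL) {
  if (!inherits(schedule, "event_schedule")) {
    stop("`schedule` must be an event_schedule")
  }
  for (side in list(rd = rd, wd = wd)) {
    for (ch in names(side)) {
      if (!inherits(side[[ch]], "phys_ts")) {
        stop("channel '", ch, "' is not a phys_ts")
      }
    }
  }
  structure(list(participant_id = participant_id, rd = rd, wd = wd,
                 schedule = schedule, rd_beats = rd_beats, wd_beats = wd_beats),
            class = "paired_recording")
}

#' @export
print.paired_recording <- function(x, ...) {
  cat(sprintf("<paired_recording> participant %s\n", x$participant_id))
  cat("  rd channels:", paste(names(x$rd), collapse = ", ") , "\n")
  cat("  wd channels:", paste(names(x$wd), collapse = ", "), "\n")
  if (!is.null(x$rd_beats)) cat(sprintf("  rd beats: %d\n", length(x$rd_beats$peak_times)))
  if (!is.null(x$wd_beats)) cat(sprintf("  wd beats: %d\n", length(x$wd_beats$peak_times)))
  print(x$schedule)
  invisible(x)
}

#' Read one channel from a two-column CSV
#'
#' Expects columns `time_s` (strictly increasing) and `value`. The sampling
#' rate is inferred from the median timestamp step unless declared. Gaps in
#' the timestamps (steps larger than 1.5 sample periods) are filled with
#' explicit `NA` samples so that missingness stays visible downstream.
#'
#' @param path file path.
#' @param channel `"eda"`, `"ecg"` or `"ppg"`.
#' @param units unit string recorded on the series.
#' @param fs declared sampling rate (Hz); inferred from timestamps if `NULL`.
#' @return a [phys_ts()].
#' @export
read_channel_csv <- function(path, channel, units = "a.u.", fs = NULL) {
  if (!file.exists(path)) stop("channel file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "value") %in% names(d))) {
    stop("channel file must have columns time_s, value: ", path)
  }
  t <- d$time_s
  if (any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1] + 1L
    stop(sprintf("non-monotone time column in %s at row %d", path, bad))
  }
  dt <- median(diff(t))
  fs_inf <- 1 / dt
  if (is.null(fs)) fs <- fs_inf
  else if (abs(fs - fs_inf) / fs > 0.05) {
    stop(sprintf("declared fs %g Hz disagrees with timestamps (%g Hz) in %s",
                 fs, fs_inf, path))
  }
  # lay values onto a uniform grid; unmatched grid points become NA
  n <- round((t[length(t)] - t[1]) * fs) + 1L
  grid <- t[1] + (seq_len(n) - 1) / fs
  idx <- round((t - t[1]) * fs) + 1L
  vals <- rep(NA_real_, n)
  vals[idx] <- d$value
  phys_ts(vals, fs = fs, start_time = t[1], units = units, channel = channel)
}

#' Write one channel to CSV
#'
#' Emits `time_s,value` rows; missing samples are skipped on write (they are
#' reconstructed as gaps by [read_channel_csv()]).
#' @param x a [phys_ts()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_channel_csv <- function(x, path) {
  stop_if_not_ts(x)
  t <- ts_times(x)
  ok <- !is.na(x$values)
  write.csv(data.frame(time_s = t[ok], value = x$values[ok]), path,
            row.names = FALSE)
  invisible(path)
}

#' Read a paired recording from a file set
#'
#' @param rd_paths,wd_paths named character vectors mapping channel name
#'   (`eda`, `ecg`, `ppg`) to a CSV path; may also contain a `beats` entry
#'   pointing at a pre-detected beat-time file (column `peak_time_s`).
#' @param schedule_path path to the event-schedule CSV.
#' @param units named character vector of units per channel; defaults are
#'   `uS` for EDA, `mV` for ECG, `a.u.` for PPG.
#' @param fs optional named numeric vector of declared sampling rates.
#' @return a [paired_recording()].
#' @export
read_recording <- function(rd_paths, wd_paths, schedule_path,
                           units = c(eda = "uS", ecg = "mV", ppg = "a.u."),
                           fs = NULL) {
  schedule <- read_schedule_csv(schedule_path)
  read_side <- function(paths) {
    chans <- list(); beats <- NULL
    for (ch in names(paths)) {
      if (ch == "beats") {
        beats <- read_beats_csv(paths[[ch]])
      } else {
        chans[[ch]] <- read_channel_csv(paths[[ch]], channel = ch,
                                        units = units[[ch]] %||% "a.u.",
                                        fs = fs[[ch]])
      }
    }
    list(chans = chans, beats = beats)
  }
  rd <- read_side(rd_paths)
  wd <- read_side(wd_paths)
  message(sprintf("recording %s: rd [%s], wd [%s]",
                  schedule$participant_id,
                  paste(c(names(rd$chans), if (!is.null(rd$beats)) "beats"), collapse = ","),
                  paste(c(names(wd$chans), if (!is.null(wd$beats)) "beats"), collapse = ",")))
  paired_recording(schedule$participant_id, rd = rd$chans, wd = wd$chans,
                   schedule = schedule, rd_beats = rd$beats, wd_beats = wd$beats)
}

#' Write a paired recording as the CSV file set [read_recording()] reads
#'
#' @param rec a [paired_recording()].
#' @param dir output directory (created if needed); files are named
#'   `<participant>_<side>_<channel>.csv` plus `<participant>_schedule.csv`.
#' @return named list of written paths, invisibly.
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pid <- rec$participant_id
  paths <- list()
  for (side in c("rd", "wd")) {
    for (ch in names(rec[[side]])) {
      p <- file.path(dir, sprintf("%s_%s_%s.csv", pid, side, ch))
      write_channel_csv(rec[[side]][[ch]], p)
      paths[[paste(side, ch, sep = "_")]] <- p
    }
    bs <- rec[[paste0(side, "_beats")]]
    if (!is.null(bs)) {
      p <- file.path(dir, sprintf("%s_%s_beats.csv", pid, side))
      write_beats_csv(bs, p)
      paths[[paste0(side, "_beats")]] <- p
    }
  }
  sp <- file.path(dir, sprintf("%s_schedule.csv", pid))
  write_schedule_csv(rec$schedule, sp)
  paths$schedule <- sp
  invisible(paths)
}
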