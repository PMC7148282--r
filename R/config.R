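#' Default analysis configuration
#'
#' Flat list of every tunable threshold in the protocol, with the defaults
#' the protocol prescribes. Override individual entries via `...` or load a
#' YAML file with [load_config()].
#'
#' @param ... named overrides of individual keys.
#' @return named list of configuration values:
#' \describe{
#'   \item{eda_fs, cardiac_fs}{comparison rates: 16 Hz for EDA, 200 Hz for
#'     beat detection.}
#'   \item{max_lag}{cross-correlation lag window in samples (8).}
#'   \item{corr_threshold}{signal-level pass threshold (.80).}
#'   \item{scr_threshold}{SCR amplitude threshold in uS (0.01; 0.001 is the
#'     exploratory lower setting).}
#'   \item{scr_min_rise, scr_max_rise}{admissible SCR rise time in s.}
#'   \item{eda_smooth_cutoff}{EDA smoothing low-pass cutoff in Hz (1).}
#'   \item{interval_bounds}{admissible RR/PP interval range in s
#'     (0.33, 1.5).}
#'   \item{sqi_long, sqi_event, min_coverage}{quality gate: SQI thresholds
#'     (70 long blocks, 80 beep windows) and consecutive-coverage fraction
#'     (0.5).}
#'   \item{sqi_window_len}{SQI window length in s (10).}
#'   \item{boundary_fraction}{a-priori boundary fraction of the plausible
#'     range (0.10).}
#'   \item{response_window}{post-beep scoring window in s (1, 6).}
#'   \item{se_multiplier}{error-bar half-width in SE units (1).}
#' }
#' @export
default_config <- function(...) {
  cfg <- list(
    eda_fs = 16,
    cardiac_fs = 200,
    max_lag = 8,
    corr_threshold = 0.80,
    scr_threshold = 0.01,
    scr_min_rise = 0.5,
    scr_max_rise = 5,
    eda_smooth_cutoff = 1,
    interval_bounds = c(0.33, 1.5),
    sqi_long = 70,
    sqi_event = 80,
    min_coverage = 0.5,
    sqi_window_len = 10,
    boundary_fraction = 0.10,
    response_window = c(1, 6),
    se_multiplier = 1
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Load configuration overrides from a YAML file
#' @param path YAML file with a flat mapping of config keys.
#' @return a config list as from [default_config()].
#' @export
load_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to load config files")
  }
  over <- yaml::read_yaml(path)
  do.call(default_config, over)
}

config_gate <- function(config) {
  list(min_coverage = config$min_coverage, sqi_long = config$sqi_long,
       sqi_event = config$sqi_event)
}

config_hash <- function(config) {
  s <- paste(names(config),
             vapply(config, function(v) paste(format(v), collapse = ","),
                    character(1)),
             sep = "=", collapse = ";")
  # small stable polynomial rolling hash; provenance only, not cryptographic
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
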