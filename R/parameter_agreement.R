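#' Derive an a-priori agreement boundary
#'
#' The acceptable device difference for a parameter is a fixed fraction
#' (default 10%, extending the 5-bpm-or-10% heart-rate equipment rule) of
#' the biologically plausible range, rounded half-away-from-zero. With the
#' default plausible ranges this yields +/- 1.6 uS (SCL, range 0-16),
#' +/- 2.5 SCR/min (0-25), +/- 0.6 uS (S-AMPL, 0-6), +/- 5 bpm (HR, 60-110),
#' +/- 0.06 s (interval SD, 0-0.56) and +/- 0.07 s (RMSSD, 0-0.71).
#'
#' @param parameter one of `"scl"`, `"scr_rate"`, `"s_ampl"`, `"hr"`,
#'   `"sd_interval"`, `"rmssd"` (free labels allowed).
#' @param plausible_min,plausible_max plausible physiological range in the
#'   parameter's units; `max > min`.
#' @param fraction fraction of the range (default 0.10).
#' @param rounding decimal places for the printed boundary (default 2).
#' @return list of class `agreement_boundary` with the inputs plus
#'   `boundary`.
#' @examples
#' derive_boundary("scl", 0, 16)$boundary   # 1.6
#' derive_boundary("hr", 60, 110)$boundary  # 5
#' @export
derive_boundary <- function(parameter, plausible_min, plausible_max,
                            fraction = 0.10, rounding = 2) {
  if (!(plausible_max > plausible_min)) {
    stop("plausible_max must exceed plausible_min")
  }
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  b <- round_half_away(fraction * (plausible_max - plausible_min), rounding)
  if (b <= 0) stop("boundary rounded to zero; increase `rounding`")
  structure(list(parameter = parameter, plausible_min = plausible_min,
                 plausible_max = plausible_max, fraction = fraction,
                 boundary = b, rounding = rounding),
            class = "agreement_boundary")
}

#' Default a-priori boundaries for the six protocol parameters
#' @return named list of [derive_boundary()] results.
#' @export
default_boundaries <- function() {
  list(
    scl = derive_boundary("scl", 0, 16),
    scr_rate = derive_boundary("scr_rate", 0, 25),
    s_ampl = derive_boundary("s_ampl", 0, 6),
    hr = derive_boundary("hr", 60, 110),
    sd_interval = derive_boundary("sd_interval", 0, 0.56),
    rmssd = derive_boundary("rmssd", 0, 0.71)
  )
}

#' Bland-Altman agreement of paired parameters
#'
#' Differences are wearable minus reference on the raw scale; limits of
#' agreement are `mean_diff +/- 1.96 sd_diff`. Percent-within is reported
#' against both the a-priori boundary and the empirical limits. Normality
#' of the differences is assessed with a Shapiro-Wilk test; when rejected
#' and the policy allows, a log transform (`log(v + offset)`) is applied for
#' the normality report only — the boundaries stay in raw units, so the
#' verdict remains on the raw scale. Pairs with a missing side are dropped
#' and counted.
#'
#' @param pairs data frame with columns `participant`, `rd`, `wd`.
#' @param boundary an [derive_boundary()] result.
#' @param transform_policy `"auto"` (log-transform the normality report when
#'   raw differences fail Shapiro at alpha 0.05), `"none"`, or `"log"`.
#' @param log_offset offset added before `log` (default 1e-3 units).
#' @return list of class `bland_altman_result`: `pairs` (with `mean_of_two`
#'   and `diff`), `mean_diff`, `sd_diff`, `loa_low`, `loa_high`,
#'   `pct_within_boundary`, `pct_within_loa`, `n`, `n_dropped`,
#'   `shapiro_p_raw`, `transform`, `shapiro_p_used`, `mean_diff_ci`.
#' @export
bland_altman <- function(pairs, boundary, transform_policy = "auto",
                         log_offset = 1e-3) {
  need <- c("participant", "rd", "wd")
  if (!all(need %in% names(pairs))) {
    stop("pairs must have columns participant, rd, wd")
  }
  ok <- complete.cases(pairs[, c("rd", "wd")])
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(sprintf("bland_altman(%s): dropped %d pair(s) with a missing side",
                    boundary$parameter, n_dropped))
  }
  p <- pairs[ok, , drop = FALSE]
  n <- nrow(p)
  if (n < 3) stop("need at least 3 complete pairs")
  p$mean_of_two <- (p$rd + p$wd) / 2
  p$diff <- p$wd - p$rd
  m <- mean(p$diff); s <- sd(p$diff)
  loa <- m + c(-1, 1) * 1.96 * s
  sh_raw <- tryCatch(shapiro.test(p$diff)$p.value, error = function(e) NA_real_)
  transform <- "none"; sh_used <- sh_raw
  if (transform_policy == "log" ||
      (transform_policy == "auto" && !is.na(sh_raw) && sh_raw < 0.05)) {
    ld <- log(p$wd + log_offset) - log(p$rd + log_offset)
    sh_used <- tryCatch(shapiro.test(ld)$p.value, error = function(e) NA_real_)
    transform <- "log"
  }
  ci <- if (s > 0) unname(t.test(p$diff)$conf.int) else c(m, m)
  structure(list(
    parameter = boundary$parameter,
    pairs = p,
    mean_diff = m, sd_diff = s,
    loa_low = loa[1], loa_high = loa[2],
    pct_within_boundary = 100 * mean(abs(p$diff) <= boundary$boundary + 1e-12),
    pct_within_loa = 100 * mean(p$diff >= loa[1] & p$diff <= loa[2]),
    n = n, n_dropped = n_dropped,
    shapiro_p_raw = sh_raw, transform = transform, shapiro_p_used = sh_used,
    mean_diff_ci = ci,
    boundary = boundary$boundary
  ), class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman> %s: n %d, mean diff %.3g, LoA [%.3g, %.3g], boundary +/-%g\n",
              x$parameter, x$n, x$mean_diff, x$loa_low, x$loa_high, x$boundary))
  cat(sprintf("  %.0f%% within boundary, %.0f%% within LoA, transform %s\n",
              x$pct_within_boundary, x$pct_within_loa, x$transform))
  invisible(x)
}

#' Per-parameter agreement verdict
#'
#' `valid` when both empirical limits of agreement lie inside the a-priori
#' band `[-boundary, +boundary]`, else `invalid`. Independently, `biased` is
#' flagged when the confidence interval of the mean difference excludes 0
#' (systematic over/underestimation by the wearable). A proportional-bias
#' diagnostic (slope of diff on mean) is reported but does not enter the
#' verdict.
#'
#' @param result a [bland_altman()] result.
#' @param boundary the [derive_boundary()] the result was built against.
#' @return list of class `parameter_verdict`: `parameter`, `verdict`
#'   (`"valid"`/`"invalid"`), `biased`, `bias_direction`, `slope`, `reason`.
#' @export
parameter_decision <- function(result, boundary) {
  b <- boundary$boundary
  valid <- result$loa_low >= -b - 1e-12 && result$loa_high <= b + 1e-12
  ci <- result$mean_diff_ci
  biased <- !(ci[1] <= 0 && ci[2] >= 0)
  direction <- if (!biased) "none" else if (result$mean_diff < 0)
    "underestimation" else "overestimation"
  slope <- if (sd(result$pairs$mean_of_two) > 0) {
    unname(coef(lm(diff ~ mean_of_two, data = result$pairs))[2])
  } else NA_real_
  reason <- sprintf(
    "limits of agreement [%.3g, %.3g] %s a-priori band [%+.3g, %+.3g]%s",
    result$loa_low, result$loa_high,
    if (valid) "lie within" else "exceed", -b, b,
    if (biased) sprintf("; mean difference CI [%.3g, %.3g] excludes 0 (%s)",
                        ci[1], ci[2], direction) else "")
  structure(list(parameter = result$parameter,
                 verdict = if (valid) "valid" else "invalid",
                 biased = biased, bias_direction = direction,
                 slope = slope, reason = reason),
            class = "parameter_verdict")
}
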