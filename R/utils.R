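# shared internal helpers

#' Round half away from zero
#'
#' Base `round()` rounds half to even; boundary derivation needs the
#' conventional half-away-from-zero rule so printed values like 0.065 -> 0.07
#' reproduce.
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Local maxima of a numeric vector
#'
#' Plateau-aware strict local maxima: a run of equal values counts as one
#' peak at its midpoint. Endpoints are never peaks.
#' @param x numeric vector (NA treated as -Inf).
#' @return integer indices of peaks.
#' @keywords internal
local_maxima <- function(x) {
  x[is.na(x)] <- -Inf
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  # collapse zero runs: direction of travel before/after each point
  s <- sign(d)
  # propagate last nonzero sign forward so plateaus inherit the approach slope
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  filled <- s
  last <- 0
  for (i in seq_len(n - 1L)) {
    if (filled[i] == 0) filled[i] <- last else last <- filled[i]
  }
  idx <- which(filled[-(n - 1L)] > 0 & s[-1] < 0) + 1L
  idx
}

#' Local minima
#' @param x numeric vector.
#' @return integer indices of troughs.
#' @keywords internal
local_minima <- function(x) local_maxima(-x)

# enforce a refractory period on candidate peak indices, preferring the
# larger amplitude when two candidates fall within `refractory` seconds
enforce_refractory <- function(idx, amp, fs, refractory) {
  if (length(idx) <= 1) return(idx)
  keep <- integer(0)
  ord <- order(idx)
  idx <- idx[ord]; amp <- amp[ord]
  i <- 1L
  while (i <= length(idx)) {
    j <- i
    while (j < length(idx) && (idx[j + 1L] - idx[i]) / fs < refractory) j <- j + 1L
    grp <- i:j
    best <- grp[which.max(amp[grp])]
    if (length(keep) == 0 || (idx[best] - keep[length(keep)]) / fs >= refractory) {
      keep <- c(keep, idx[best])
    }
    i <- j + 1L
  }
  keep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# zero-phase filtering with odd (point-reflection) padding at both ends to
# suppress filtfilt start-up transients on non-zero-mean segments
filtfilt_padded <- function(bf, seg, pad) {
  pad <- min(length(seg) - 1L, as.integer(pad))
  if (pad < 1) return(signal::filtfilt(bf, seg))
  nl <- length(seg)
  left <- 2 * seg[1] - seg[(pad + 1):2]
  right <- 2 * seg[nl] - seg[(nl - 1):(nl - pad)]
  y <- signal::filtfilt(bf, c(left, seg, right))
  y[(pad + 1):(pad + nl)]
}
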