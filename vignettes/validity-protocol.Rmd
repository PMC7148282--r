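---
title: "A three-level validity protocol for wearable physiological sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-level validity protocol for wearable physiological sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physioval)
```

## The problem and the model

Validating a wearable sensor against a laboratory reference device is a
method-agreement problem, not a correlation problem: two devices can
correlate highly while one systematically under-reads, and they can agree on
per-person averages while disagreeing on the stress responses a study
actually targets. `physioval` therefore assesses agreement on three levels
with criteria fixed *before* looking at the data.

**Signal level.** Both EDA signals are brought to a common 16 Hz grid
(EDA carries no useful information above a few hertz; reference devices
often sample at 256 Hz, wrist wearables at 4 Hz), detrended with a single
least-squares line (a stationarity prerequisite for cross-correlation), and
z-normalized (offset and gain at different recording sites are not the
phenomenon of interest). The Pearson correlation is computed at each integer
lag in ±8 samples (±0.5 s at 16 Hz — a deliberately generous window for
sympathetic conduction delay between wrist and fingertips, which is at most
about 0.18 s) on the overlapping non-missing samples of each lag. The
cohort passes only when every participant's best correlation exceeds .80:
below that, the *source* of disagreement cannot be identified, so nothing
can be corrected. On a pass, a residual mean or variance difference is a
removable calibration bias (`mean_bias_adjust()`), and validity of the
derived levels is implied. ECG and PPG are different waveforms by
construction, so a signal-level comparison between them is refused as
`not_applicable` rather than computed and failed.

**Parameter level.** Six per-participant parameters are compared with
Bland–Altman analysis: differences are wearable − reference on the raw
scale, limits of agreement are mean ± 1.96 SD, and the verdict is `valid`
only when both limits lie inside an a-priori boundary declared before
analysis. The boundary rule is 10% of the biologically plausible range of
the parameter, generalizing the established
5-beats-per-minute-or-10% rule for heart-rate equipment:

```{r boundaries}
t(vapply(default_boundaries(), function(b)
  c(min = b$plausible_min, max = b$plausible_max, boundary = b$boundary),
  numeric(3)))
```

Rounding is half-away-from-zero at two decimals, which reproduces the
conventional printed values (e.g. 10% of 0–0.56 s → ±0.06 s). Normality of
the differences is assessed (Shapiro–Wilk plus the plots); when rejected, a
log transform is applied *to the normality report only* — the boundaries are
declared in raw units, so the verdict stays on the raw scale. A mean
difference whose confidence interval excludes zero is flagged `biased`
(over/underestimation) independently of the validity verdict, and a
diff-on-mean slope is reported as a proportional-bias diagnostic.

**Event level.** The stress parameters are SCR total amplitude (EDA) and
mean instantaneous heart rate (CVA). A stressor effect exists when the
baseline and task mean ± 1·SE bars are disjoint — deliberately the informal
error-bar rule rather than a t-test, because the protocol targets robust
effects and transparent plots. Only when the *reference device* detects the
effect can the wearable be judged; the acceptance band for the device
difference is the reference effect itself (the RD's baseline-to-task
difference): a wearable biased by more than the effect it is supposed to
detect cannot distinguish task from baseline. The decision order per task:
RD no effect → `inconclusive`; wearable data insufficient →
`inconclusive_data`; RD effect but no WD effect → `invalid`; both effects
but the difference bar misses zero or exceeds the band → `invalid`;
otherwise `valid`.

Comparison windows are matched in length: the task baseline is the trailing
sub-window of the first baseline block cut to the stressor length, and the
beep baseline is a response-window-length slice just before the noise block.
Total amplitude grows with window length, so unequal windows would
manufacture spurious effects.

## Feature extraction choices

* **SCR scoring** is classical trough-to-peak on the smoothed signal: each
  local maximum is paired with the onset of its monotone rise; the pair is
  an SCR when the rise is ≥ 0.01 µS (0.001 µS available as an exploratory
  setting) and takes 0.5–5 s. Events never overlap or share a trough, and
  detection is invariant to constant offsets. Smoothing is a zero-phase
  2nd-order Butterworth low-pass at 1 Hz (configurable; scoring programs
  differ in their defaults), verified to attenuate a 5 Hz tone by > 95%
  while overshooting a step by < 5%.
* **Nonresponders** (no SCRs anywhere in the recording, on either device)
  are excluded from all cohort analyses. This is an automated surrogate for
  the visual two-rater screen used in laboratory practice; it catches flat
  recordings but not subtler artifact classes a human rater would.
* **Beat processing**: 5–15 Hz zero-phase band-pass; adaptive-threshold
  peak picking (ECG) or prominence-based local maxima (PPG) with a 0.25 s
  refractory period; RR/PP intervals outside 0.33–1.5 s are deleted from
  the interval multiset (the beats stay, so neighbouring intervals are
  unaffected). RMSSD uses N − 1 successive differences over N intervals.
* **Quality gating**: the published signal-quality indices for PPG are
  cited in the field without closed-form definitions, so the package
  implements a self-contained template-correlation SQI — each beat's
  waveform is correlated with the window's mean beat, scaled to 0–100 and
  zeroed when the window's rate or interval ratio is implausible — plus a
  beats-only regularity surrogate for inputs supplied as pre-detected beat
  times. A block is accepted when a *consecutive* run of windows at or
  above threshold (70 for long blocks, 80 for beep windows, where only a
  handful of beats exist and each must be trustworthy) covers ≥ 50% of it.
  Whether "50% of the block" counts samples or windows is ambiguous in
  practice; windows are used here.
* **Habituation** is fitted by ordinary least squares of log mean amplitude
  on stimulus index, after subtracting the matched-baseline floor (the
  spontaneous-SCR contribution inside each post-beep window, which would
  otherwise flatten the decay); the decay rate is 1 − exp(slope). A
  descriptive per-stimulus percentage is deliberately chosen over a mixed
  model: the protocol's audience is meant to read every number off a plot.

## The synthetic cohort

`simulate_cohort()` generates the study conditions end to end: a sing-a-song
schedule (160 s baseline, 30 s anticipation, 30 s singing, 120 s recovery)
followed by a 300 s noise task containing 26 200-ms beeps with gaps ≥ 7 s
(drawn once per seed, as a real experiment fixes one stimulus sequence for
all participants), then a 120 s recovery.

* **EDA**: tonic level (4 µS ± 0.5 between participants) with a slow drift,
  spontaneous SCRs from a renewal process (3 s refractory + exponential,
  mean rate 4/min — mid-range between resting and high-arousal rates) with
  bi-exponential kernels (~1.2 s rise), amplitudes 0.4 ± 0.1 µS scaled by a
  lognormal per-participant factor (log-sd 0.3), tripled rate and amplitude
  during anticipation/singing, and beep responses of 0.5 µS decaying 4% per
  stimulus with 1.2–2.2 s latency. Sensor noise is 0.001 µS, the
  quantization-scale noise of modern EDA sensors. The wearable re-expresses
  the same event stream at 4 Hz with configurable attenuation, a separate
  attenuation for beep-evoked responses (a wrist site can track sustained
  arousal yet miss small phasic stimuli), per-participant gain spread, slow
  site-specific tonic distortion, lag, and its own noise.
* **CVA**: intervals follow a stationary Gaussian AR(1) with variance set
  to the target SD and autocorrelation 1 − RMSSD²/(2 SD²), which makes the
  expected RMSSD equal its target; the singing block adds 19.8 bpm. The
  wearable re-observes the reference beats with 3 ms jitter and loses
  burst-length slots covering the configured dropout fraction.

What the generator does *not* emulate: waveform morphology beyond what beat
detection needs, motion artifacts, thermoregulatory drift, respiratory
sinus arrhythmia structure, or nonstationary tonic dynamics. Passing tests
on this cohort therefore demonstrate that the *pipeline and decision logic*
behave as specified under known ground truth — not that any particular
device is valid on real skin.

## Numerical choices and degenerate inputs

Time is seconds from recording start; block intervals are half-open
[onset, offset), so adjacent blocks partition a recording exactly.
Up-sampling is linear interpolation; down-sampling applies a zero-phase
anti-alias low-pass at 0.45× the target rate before interpolation, with odd
reflection padding so filter transients stay below ~10⁻⁴ at the very edges
(interior round-trip error is < 10⁻⁶ for band-limited content). Missing
samples are explicit `NA`s that propagate as gaps: filters process each
non-missing run separately, resampling never interpolates across a gap, SCR
rates divide by non-missing duration, and Bland–Altman pairs with a missing
side are dropped *and counted*. Cross-correlation ties are broken toward
the smallest |lag|, then negative. Zero-variance channels, all-missing
series, infeasible beep schedules, windows without samples and cohorts
below n = 3 are refused with informative errors; insufficient intervals
yield `NA` parameters, never silent zeros.

Problem sizes in the tests and acceptance script — cohorts of 15–60
participants, 200 lag-recovery trials, 10,000 Bland–Altman pairs, 200
habituation replicates — were chosen to keep Monte-Carlo error comfortably
inside each tolerance while the full suite runs in well under a minute.

## Known limitations

* The ±1·SE zero-crossing rule has an intrinsic false-alarm floor: for iid
  mean-zero device differences the t statistic is pivotal, so even a
  perfectly unbiased wearable crosses zero with only ≈ 2/3 probability, at
  any cohort size. The verdict-path simulations reproduce this (the
  sustained-stressor outcome is reported as a rate over replicate cohorts);
  users wanting a stricter error rate can raise `se_multiplier`, at the
  cost of leaving the protocol's canonical criterion.
* A signal-level pass short-circuits the tree; with a 4 Hz wearable this is
  nearly unreachable on real data, which is by design — the lower levels
  exist precisely because of it.
* The nonresponder rule, SQI formulation, smoothing defaults and the
  habituation estimator are reasoned stand-ins for under-specified
  laboratory conventions; all are configurable and recorded in the verdict's
  config hash.
* Frequency-domain heart-rate-variability measures are out of scope: the
  short stressor blocks the protocol uses cannot support them reliably.
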