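---
title: "Methods: dopamine signal processing and behavioral metrics in striatr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dopamine signal processing and behavioral metrics in striatr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatr)
```

striatr packages the analysis chain of a typical in-vivo striatal dopamine
study: fiber photometry with a dLight-class fluorescent dopamine sensor
during operant behavior, ex-vivo fast-scan cyclic voltammetry (FSCV) of
evoked dopamine transients, piezo-based home-cage rest-activity monitoring,
and operant/gustometer behavioral session logs. Every stage is paired with
a synthetic-data generator carrying explicit ground truth, so the whole
chain is testable without access to recordings. This vignette documents the
models, the parameters that matter, the numerical choices, and what the
synthetic world does and does not establish.

## 1. Photometry: isosbestic correction, dFF, z-scoring

The acquisition model is a two-channel recording: a 465 nm channel carrying
both dopamine-dependent sensor fluorescence and artifacts, and a 405 nm
isosbestic channel carrying only the artifacts (motion, photobleaching).
Processing follows the standard recipe:

1. **Downsample** by block means (default factor 10 from a 1017 Hz
   acquisition to 101.7 Hz). Block averaging rather than decimation is used
   because it is anti-aliasing-safe for input already low-passed at 6 Hz by
   the demodulation hardware; with such input the two differ negligibly,
   and the package's tests bound the discrepancy between
   downsample-then-dFF and dFF-then-downsample at 0.1 dFF%.
2. **Fit the reference**: one ordinary-least-squares regression of the
   465 nm signal on the 405 nm reference over the whole session,
   $\widehat{F}_{405}(t) = \beta_1 F_{405}(t) + \beta_0$. A single
   session-wide fit is used — no rolling or piecewise fits — matching the
   single fitted control of the conventional pipeline.
3. **dFF**: $\mathrm{dFF}(t) = 100\,(F_{465}(t) - \widehat{F}_{405}(t)) /
   \widehat{F}_{405}(t)$, in percent. A non-positive fitted baseline
   anywhere is an explicit error (the first offending time is reported),
   not a silent NaN.
4. **z-score** over the full session, including inter-trial intervals,
   with the population (divide-by-$n$) convention. The normalization
   window is a genuine free choice — the field rarely states it — and
   full-session is the default here because it makes the z-scored scale
   comparable between task and drug sessions.

Two identities pin the implementation down: with zero noise and zero
transients the 465 channel is an exact affine image of the 405 channel, so
dFF must vanish to numerical precision; and dFF is invariant both to a
common multiplicative gain on the two channels and to any affine
transformation of the reference (the regression refits). Both are tested.

Non-uniform time grids are rejected rather than resampled; resampling
policy is an acquisition question, not an analysis one.

## 2. Peri-event analysis

Trials are extracted on a common relative-time grid around a named event
(lever extension, dipper presentation, reward delivery). Trials whose
window exceeds the recording are dropped and counted, never padded. The
per-trial baseline is the mean over $[-5, -0.5]$ s before the alignment
event — the inter-trial interval — and is subtracted row-wise.

Metric windows are event-specific: 0–1.5 s after lever extension, 0–1 s
after dipper presentation, 0–3 s after reward delivery, overridable per
call. AUC is the trapezoidal integral of the trial-averaged corrected
trace over the window; by linearity it equals the mean of per-trial AUCs,
which is asserted in tests. Peak height is the maximum of the averaged
corrected trace in the window, reported only when it exceeds one standard
deviation of the local (ITI) baseline; "local baseline" is operationalized
as the trial's own baseline window since no tighter definition is
standard.

**Spontaneous transients.** Within each ITI span, local maxima of the
z-scored dFF are retained when their topographic prominence exceeds
2 session standard deviations. The conventional phrasing ("prominence
exceeding two standard deviations above the session mean") conflates a
relative quantity (prominence) with an absolute level (mean + 2 SD); the
package implements the prominence reading by default and the height
reading as `mode = "height"`. Peak width is full width at half prominence
with linear interpolation. Events closer than the 4 s report window are
both kept; their windows may overlap. Detection is deliberately
smoothing-free — the input is already band-limited — and the detector is
required by test to agree exactly with an exhaustive
walk-outward-from-each-peak oracle.

**Amphetamine sessions.** The drug-session trace is summarized by the mean
z-scored dFF over the post-injection horizon, the OLS slope of the rising
phase, and the latency to plateau. "Plateau" has no standard definition;
here it is the first time the 60 s moving average reaches 95% of its
post-injection maximum and stays there for 120 s, with all three constants
exposed as arguments. The slope is fit from injection to plateau onset
(or the whole horizon if no plateau is reached, flagged). On a noiseless
logistic rise the detected latency falls within one smoothing window of
the analytic 95% crossing, which is the tested contract.

## 3. FSCV transient quantification

The package consumes the extracted transient time course (one
concentration point per voltammogram; 10 Hz for the standard 100 ms
waveform repetition), not raw voltammograms. Calibration multiplies
current by the µM-per-pA factor from a 1 µM dopamine standard; calibrating
twice is an explicit error. The command-waveform helper reports the
scan-rate magnitude of a symmetric triangle, $2(V_{max} - V_{min})/T$
(≈294 V/s for −450 mV → +800 mV in 8.5 ms).

Quantification: baseline = mean of the 1 s pre-stimulus window; Imax =
post-stimulus maximum minus baseline, required to exceed baseline + 3
pre-stimulus SDs; Tau1 from a bounded nonlinear least-squares fit of
$b + a\,e^{-(t-t_{peak})/\tau}$ starting at the peak, seeded by log-linear
regression on the early decay and refined by L-BFGS-B with
$\tau \in (1\,\mathrm{ms}, 60\,\mathrm{s})$. A single exponential is used
because a single clearance constant is the conventional readout; no
Michaelis–Menten reuptake model is fit.

**Fit window.** The natural-looking rule — truncate the fit where the
trace returns within 5% of the peak of baseline — turns out to be
information-starved at 10 Hz: it discards the tail that anchors the free
offset $b$, and simulation shows the truncated fit sits at its Cramér–Rao
limit *above* a 5% median error at realistic amplitudes
(SNR 10 at the smallest grid amplitude). The default therefore fits from
the peak to the end of the sweep (`fit_end = "sweep_end"`), roughly
halving the Tau1 error; the truncating variant is retained as
`fit_end = "baseline_return"` (with the return judged on a 3-point running
median so one noisy sample cannot end the segment) for traces whose tails
drift. The sensitivity comparison is part of the test suite.

Session summaries follow the middle-three convention (a pulse every 2 min
for 10 min; the three middle peaks analyzed): positions
$\lceil n/2 \rceil - 1 \ldots \lceil n/2 \rceil + 1$, which biases toward
earlier sweeps on even counts — the protocol is ambiguous about 5 vs 6
pulses and an explicit tie rule beats an implicit one.

## 4. Circadian statistics

Activity arrives as normalized movement intensity per 10-min epoch,
clipped to [0, 0.3], with a binary sleep state and a 12:12 light schedule
(lights on 06:00, ZT0). IS and IV use the standard nonparametric
actigraphy definitions on hourly bins ($p = 24$):

$$IS = \frac{N \sum_h (\bar{x}_h - \bar{x})^2}{p \sum_i (x_i - \bar{x})^2},
\qquad
IV = \frac{N \sum_{i \ge 2} (x_i - x_{i-1})^2}{(N-1) \sum_i (x_i - \bar{x})^2}.$$

The published limits anchor the implementation: IS = 1 for a noiseless
trace locked to a 24-h zeitgeber; IV → 0 for a smooth sinusoid
(analytically $2(1 - \cos(2\pi/p))$ at $p$ bins/day, i.e. ≈0.034 at hourly
bins and ≈$1.9\times10^{-5}$ at 1-min epochs) and IV → 2 for Gaussian
white noise. Whether the original analyses binned hourly or used raw
epochs is not stated anywhere authoritative; hourly is the default and
`bin = "epoch"` is available. Days with missing epochs are excluded
wholesale — no imputation. Both statistics are affine-invariant and are
required to match brute-force double-loop implementations to 1e-12.

For the i.i.d.-noise null, note that $E[IS] \approx p/N$ (1/`n_days`),
not a universal 1/24; the suite checks this at 24 recorded days where the
two coincide.

Phase summaries report percent time asleep, mean sleep-bout duration
(maximal runs of sleep state 1), mean activity, and activity amplitude
(mean activity over awake epochs) per phase. Bouts spanning a light/dark
boundary are split at the boundary by default (`boundary = "onset"`
assigns them to their starting phase) — splitting keeps per-phase sleep
time and bout time consistent.

## 5. Operant and gustometer metrics

Sessions are normalized event logs (`lever_extension`, `lever_press`,
`dipper_up`, `dipper_down`, `head_entry`). Reward "consumption" is
operationalized as at least one head entry during the dipper-up period;
no other detection rule is defensible from an event log. Missing
latencies are excluded from means, never imputed, and counted. "Average
latency to lever press" averages over all presses by default
(`mean_press_over = "first"` gives the per-trial-first variant); the
field's usage is ambiguous.

The fixed-interval scallop curve pools presses within
$[\mathrm{extension}, \mathrm{extension} + \mathrm{FI})$ across trials
into equal bins; bin rates conserve the total in-interval press count by
construction. Every metric is required to equal a brute-force recount of
the raw event table on hundreds of random synthetic sessions.

Gustometer metrics distinguish a concentration with *no completed trials*
(reported `NA`) from one with zero licks on completed trials — completed
means at least one lick, so the latter cannot occur, and the distinction
matters when sessions are short.

## 6. The synthetic world

The generators state the world the tests run in:

* **Photometry**: shared single-exponential bleaching (tau 1200 s, 30% of
  a 100 a.u. baseline) and shared exponentially decaying motion bumps in
  both channels, channel gain 1.5, signal offset 20 a.u.; dopamine
  transients only in the 465 channel, multiplicative on local fluorescence
  so amplitudes are stated directly in dFF%. The transient kernel is a
  difference of exponentials (0.1 s rise, 0.8 s decay) — no authoritative
  kernel exists, and these constants give the sub-second peaks
  characteristic of dLight kinetics. No SNR figure exists either;
  noise is a free parameter and the recovery tests state theirs (SNR ≥ 5).
* **FSCV**: linear 0.2 s rise to the peak, exact exponential clearance,
  10 Hz sampling, optional Gaussian noise. Sampled at the voltammogram
  repetition rate because that is what the extracted time course is.
* **Activity**: baseline 0.15 + amplitude 0.1 cosine peaking at mid-dark
  (ZT18), 10-min epochs, clipped to [0, 0.3]; optional day-to-day phase
  jitter degrades IS controllably, additive noise raises IV. Sleep state
  is thresholded at the series midline. The square waveform gives the
  light/dark step profile.
* **Operant**: CRF/FI/trough logs with exponential (or deterministic)
  press and retrieval latencies, variable ITIs (uniform 0.5–1.5× the
  protocol mean: 20 s CRF, 12 s FI, 30 s trough), in-interval FI presses
  from an inhomogeneous Poisson process via thinning against a
  rate-profile function — linear-increasing by default, which is what
  produces scalloping. Unanswered trials time out after 60 s.
* **Licks**: balanced shuffled blocks over the six standard concentrations
  (0–100% evaporated milk), engagement probability per trial, first lick
  after an exponential latency then Poisson licking at 6 Hz for the 5 s
  access window, 20 s ITI.
* **Amphetamine**: logistic rise of z-scored dFF to a plateau
  (default plateau 8 z-units, rate 0.01 /s, midpoint 300 s) — plausible
  magnitudes for a 1-h post-injection horizon; chosen once, not fit to
  anything.

All randomness flows from one explicit seed per generator call and the
caller's RNG stream is restored afterward; fixed seed implies
byte-identical output.

**What a green suite establishes — and what it does not.** The tests
establish that the implementations compute their stated definitions
(oracle equivalence), satisfy the published limiting values, and recover
known parameters from data generated *under the stated model*. They do not
establish performance on real recordings: real photometry has
wavelength-dependent bleaching that violates the shared-structure
assumption, hemodynamic and spectral cross-talk, and non-Gaussian noise;
real FSCV tails drift with electrode polarization; real sleep scoring is
imperfect upstream of these metrics. Group-level biological comparisons
(genotype effects and their statistics) are deliberately out of scope.

## 7. Numerical conventions

* Population SD everywhere a session SD is meant; sample SD only inside
  OLS standard-error contexts.
* Trapezoidal integration on the downsampled grid for all AUCs; a
  discrete rectangle therefore loses half a sample at each edge, and
  tests carry that tolerance explicitly.
* Alignment snaps event times to the nearest sample; no sub-sample
  interpolation.
* Ties in peak detection: strict local maxima only (plateau samples do
  not produce duplicate peaks on continuous-valued data).
* Degenerate inputs fail loudly with typed conditions
  (`striatr_invalid_parameter`, `striatr_degenerate_fit`,
  `striatr_no_transient`, ...), never silently.
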