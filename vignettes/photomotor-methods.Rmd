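---
title: "Methods: from multiplexed photodetector voltage to peri-event statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multiplexed photodetector voltage to peri-event statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photomotor)
```

This vignette documents the models, parameter choices and numerical
decisions behind `photomotor`. It is the place where design questions that
had more than one defensible answer are recorded together with the answer
we chose and why.

## The measurement model

A frequency-multiplexed fiber-photometry rig drives two excitation LEDs
with sinusoidal intensity modulation — the Ca²⁺-sensitive 465 nm channel at
211 Hz and the isosbestic 405 nm channel at 531 Hz — and collects both
fluorescence responses on one photodetector. The voltage is

$$v(t) = E_{ca}(t)\,\sin(2\pi\,211\,t) + E_{iso}(t)\,\sin(2\pi\,531\,t) + \varepsilon(t),$$

where the envelopes carry the biology:

$$E_{ca}(t) = b(t)\,\bigl(B_{ca} + c(t) + m\,a(t)\bigr), \qquad
  E_{iso}(t) = b(t)\,\bigl(B_{iso} + a(t)\bigr).$$

Here $c(t)$ is the Ca²⁺ transient trace, $a(t)$ a motion artifact shared by
both channels, $m$ the relative gain with which the artifact appears in the
Ca²⁺ channel (the *mixing coefficient*), $b(t)$ a multiplicative
photobleaching decay, and $B_{\cdot}$ the LED baselines. Every term of this
model is something the pipeline must undo: demodulation recovers the
envelopes, the isosbestic fit removes $m\,a(t)$, the high-pass removes
$b(t)$, and the Z-score removes the remaining scale and offset.

The synthetic generator (`synthesize_session()`) instantiates exactly this
model and exports every injected component, which is what makes each
processing stage testable against ground truth rather than against itself.

## Demodulation

`lockin_demodulate()` performs quadrature demodulation: multiply by
reference sine and cosine at the carrier, low-pass both products
(4th-order Butterworth), return $2\sqrt{I^2+Q^2}$. Taking the magnitude
makes the recovery independent of the carrier phase, which matches how a
hardware lock-in with no phase reference behaves. The other carrier lands
at the 320 Hz difference frequency and is annihilated by the low-pass; the
measured cross-channel leakage is below $10^{-20}$ in power.

Decisions:

* **Demodulation bandwidth 10 Hz.** The acquisition hardware's true
  bandwidth is not knowable from the outside; 10 Hz sits comfortably above
  the indicator kinetics (sub-second decay → a few Hz) and far below half
  the 320 Hz carrier separation. It is a declared default, not a
  reproduction of any particular instrument.
* **Output rate 100 Hz**, by linear interpolation of the 10 Hz-band
  envelope — alias-free by construction.
* **Settling flags**: the first and last second of each demodulated trace
  are flagged and excluded from Z-score statistics.
* **Filter initialization at the mixer product's one-cycle mean.** A
  digital filter must assume some pre-signal history. Initializing at the
  first raw sample of the product (an arbitrary point of a 211 Hz
  oscillation) puts the first envelope samples off by the order of the
  baseline itself; that error then relaxes through the much slower
  detrending high-pass downstream and contaminates the first minute of the
  recording. Initializing at the product's mean over one carrier cycle
  (its true local DC) removes the problem at the source.

## Zero-phase filtering

All detrending/smoothing runs forward–backward (`zero_phase`), so filters
contribute no group delay: event latencies — the core readout of peri-event
alignment — are preserved. A `causal` mode is retained for sensitivity
analysis; the test suite demonstrates that it shifts transient peaks while
the zero-phase path does not.

The high-pass cutoff of 0.0051 Hz corresponds to a ~196 s period, which is
extreme for a 600 s recording, and the edge behavior of naive
forward–backward filtering (zero internal state) is unusable at that
cutoff: a constant input produces transients that decay over minutes. The
package therefore implements steady-state forward–backward filtering on top
of `signal::butter()` designs:

* **Step initial conditions**: each pass starts as if a constant level had
  been applied forever; the level is estimated as the *median* of the
  signal over the filter's memory span (five times the slowest pole's time
  constant). The median matters: sparse positive Ca²⁺ transients near a
  boundary would bias a mean estimate.
* **Even (symmetric) reflection padding**, half a cutoff period long for
  the high-pass. Odd (point) reflection — the textbook default — turns the
  positive transients near a boundary into *negative* spikes inside the
  pad, and the slow high-pass smears those back into the first and last
  minute of the signal as baseline swings of several tenths of a Z unit.
  Even reflection preserves the local level and the sign of transients, and
  its slope discontinuity at the joint is negligible for these cutoffs.
  The residual edge bias is below 0.05 Z units.

With this machinery the measured contracts hold tightly: DC residual after
the high-pass $< 2\times10^{-6}$, measured −3 dB points at 0.00510 and
2.290 Hz, zero-phase gain 0.49997 at the nominal cutoff (the squared
single-pass −3 dB magnitude, i.e. 0.5).

## Isosbestic subtraction

Two variants are provided. `direct` subtracts the isosbestic envelope
as-is; `fitted` (the default) subtracts the affine least-squares projection
of the isosbestic onto the Ca²⁺ channel. Plain subtraction is wrong
whenever the two channels see the artifact with different gains ($m \ne
1$), which is the generic case; the fitted variant recovers $m$ to within
0.05 on synthetic mixtures and its residual correlates $> 0.99$ with the
injected transient trace. When the channels also share a strong bleaching
drift the fitted slope compromises between the artifact gain and the
baseline ratio; the high-pass afterwards removes what the compromise
leaves. The fit runs over the full recording; a zero-variance isosbestic
falls back to direct subtraction with a warning.

## Z-score

`z = (x − mean)/SD` with the sample (n−1) SD, computed over the scored span
(settling margins excluded) and applied to the whole trace. The convention
is pinned so tests can be exact; at $n \approx 6\times10^4$ the n vs n−1
distinction is irrelevant in practice. Recordings shorter than 600 s
trigger a warning from the detrending stage because the 196 s high-pass
period makes detrending unreliable on short traces.

## Behavior

* **Calibration**: cm/px scale from the mean of the four tracked arena-side
  lengths; the corner polygon (not the nominal square) defines
  arena containment, tolerating camera perspective.
* **QC order**: likelihood < 0.8 (strict), then outside-arena, then implied
  step speed > 334 cm/s — each frame is counted against the first rule it
  fails, and retained + excluded counts always sum to the frame count. The
  speed rule runs sequentially against the last retained frame so one bad
  jump does not cascade.
* **Speed**: defined only between consecutive valid frames; QC gaps are not
  interpolated (no interpolation rule is defensible without knowing the
  tracker's failure mode), so the frame after a gap has no speed.
* **Bouts**: maximal runs of frames with speed strictly > 3 cm/s whose
  duration, counted as (last − first) + one frame period, is ≥ 0.5 s. The
  one-trailing-frame convention means exactly 10 frames at 20 fps qualify;
  it is pinned so the detector can be tested for exact equality against a
  brute-force enumeration. No gap bridging: any sub-threshold or missing
  frame ends a run — the strictest reading, chosen because no merging rule
  is stated anywhere authoritative.
* **Responses**: a trial is responsive when a bout *starts* within 5 s of
  the stimulus; "displayed a locomotor response during the 5 s after" is
  read as response initiation. An `overlap` mode (any bout overlapping the
  window) is available behind a flag.

## Alignment

Stimulus epochs are resampled by linear interpolation onto an exact
−5…+10 s axis at the signal rate — interpolation rather than
nearest-sample snapping, because alignment points (e.g. the 0.803 s
visual-looming offset, where disk expansion turns exponential) need not
fall on the sample grid. Companion speed is averaged into 50 ms bins.
Trials whose window leaves the recording are dropped with a warning
(padding would manufacture data); row counts plus drops always equal the
event count.

Motor-event epochs use duration-normalized time $u = (t -
\text{onset})/D$: onset at 0, offset at 1, window −0.5…1.5, with bin edges
anchored exactly on 0 and 1 (the scientifically meaningful landmarks). Bin
widths are 0.002 for photometry and 0.05 for the motor parameter. For
short bouts the photometry grid is finer than the sample spacing; empty
bins are recorded as missing and ignored when averaging across bouts.
Overlapping windows from closely spaced bouts are all kept — samples may
legitimately serve two events; no exclusion rule is imposed.

Window means are arithmetic means over left-closed right-open windows
([a, b)), so shared endpoints are never double-counted: stimulus scheme
(−5,0), (0,5), (5,10) s; motor scheme (−0.5,0), (0,0.5), (0.5,1), (1,1.5)
in normalized time.

## Statistics

The branch gates mirror the conventional decision tree: Shapiro-Wilk per
window and Levene across windows (classic mean-centered Levene; the robust
median-centered variant is a different test), both at α = 0.05. Passing
both selects the one-way repeated-measures ANOVA (`aov` with a subject
error stratum); failing either selects the Friedman ANOVA on ranks. A
significant omnibus is followed by the Student-Newman-Keuls stepwise
procedure: ordered means, studentized-range statistic
$q = \Delta/\sqrt{MS_e/n}$ at the span of each comparison, and the classic
protection rule that a non-significant range leaves everything it encloses
untested. On the rank branch the same scheme runs on within-subject rank
sums with $SE = \sqrt{nk(k+1)/12}$ and infinite error df. No sphericity
correction is applied to the RM-ANOVA — a known limitation, recorded here
deliberately.

Both branches are calibrated: under 2000 null replicates (10 subjects × 3
windows, i.i.d. normal) the rejection rates are ~0.052 (parametric) and
~0.042–0.047 (Friedman; slightly conservative at this n because its χ²
reference is asymptotic). SNK decisions agree exactly with a direct
table-lookup oracle on 3-group instances.

Regressions are ordinary least squares. The speed regression averages
Z-score and speed per bout, bins bouts into 1 cm/s classes, and regresses
per-bin mean Z on bin-center speed. The habituation regression averages the
during-window response per trial index across mice *before* fitting —
matching an analysis that reports a single R² per cell type — and reads
percent change off the fitted line, $100\,(\hat y_j - \hat y_i)/\hat y_i$,
which is robust to single-trial noise (computing it from raw trial means is
the obvious alternative; the fitted-line version is declared and used
consistently). Within-series trial index is used, averaged across series.

## The synthetic generator: what it emulates, and what it does not

Defaults describe the emulated recording regime: 600 s sessions, 10 stimuli at
60.1 ± 0.3 s spacing (jitter truncated at ±2 SD so spacing stays in the
stated regime), 20 fps camera over a 40 × 40 cm arena at 10 px/cm, raw
sampling at 6103.52 Hz, carriers 211/531 Hz. Free parameters were fixed
once at field-realistic values:

* **Transient kernel**: difference of exponentials, rise τ 20 ms, decay τ
  200 ms, peak-normalized, amplitude 5 — jGCaMP7f-class kinetics. The
  ground truth records both event onsets and analytic *peak* times; peak
  recovery is judged against the latter, since the 2.29 Hz zero-phase
  smoothing deterministically moves the observed peak ~80 ms from onset
  but only that far from the kernel peak.
* **Bleaching**: double exponential, time constants 300 s and 2000 s
  (amplitudes 0.1 each). Both sit well below the 0.0051 Hz high-pass
  corner, consistent with the design premise that detrending removes
  bleaching; a faster component would simply pass the filter and belong to
  the artifact budget instead.
* **Motion artifact**: 0.5 Hz-band Gaussian noise, SD 0.05 V, injected
  into both channels with mixing coefficient 1.5 — the premise that makes
  isosbestic subtraction recoverable and testable.
* **Spontaneous transients** at 0.02 events/s with a 2 s refractory
  separation: overlapping events would merge into one peak and the truth
  list would stop being a usable oracle.
* **Responders**: a configurable fraction of trials receives a
  stimulus-locked transient (0.3 s latency, amplitude scaled by the
  per-trial habituation multiplier) and an evoked bout starting inside the
  5 s response window; spontaneous bouts and transients are kept clear of
  all response windows so the ground-truth flags stay exact.
* **Trajectories** are concatenated constant-speed frame steps with a
  smoothly wandering heading, reflected off a 2 cm wall margin; bout plans
  are snapped to the frame grid so the detector recovers the truth
  intervals exactly on the noiseless track. Tracking noise defaults to
  zero; a `noise_px` parameter exists but the exactness guarantees only
  hold without it.

Not emulated: acoustics of the stimuli, video rendering, pose-estimation
failure modes (occlusion, identity swaps), hemodynamic contamination,
indicator nonlinearity and saturation, and inter-animal variability beyond
what seeds provide. Passing the round-trip tests therefore shows the
*pipeline arithmetic* is right under the stated measurement model; it does
not certify performance on real rigs whose artifacts violate that model.

## Problem sizes used in verification

The shipped verification battery uses: one 600 s round-trip session per
seed; 1000 random traces for the detector/oracle equivalence; 2000 null
replicates per omnibus branch; 200 three-group instances for the SNK
oracle; 20 pooled sessions for habituation recovery (the programmed −50 %
decline is recovered at ≈ −55 %, the extra ≈ 5 points being the genuine
bleaching decline that multiplies the injected transients); and 200
lightweight speed-coupled sessions for slope recovery (bias ≈ 1 %). These
sizes give Monte-Carlo standard errors comfortably inside the tolerances
they are checked against.

## Known limitations

* Edge bias of the 0.0051 Hz high-pass is reduced, not eliminated: the
  first/last ~30 s of a recording carry a residual baseline uncertainty of
  a few hundredths of a Z unit.
* The Friedman branch is conservative at small n (asymptotic χ²).
* No sphericity correction in the RM-ANOVA; no mixed-effects alternative
  for the habituation analysis (per-index averaging across mice is the
  declared aggregation).
* The isosbestic fit is global; piecewise or robust fits for non-stationary
  artifact coupling are out of scope.
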