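---
title: "Models and methods: dopamine photometry, voltammetry and operant analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: dopamine photometry, voltammetry and operant analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopaflow)
```

`dopaflow` implements three analysis streams used when studying drug reward
in the mesolimbic dopamine system: fluorescent dopamine-sensor fiber
photometry in behaving animals, fast-scan cyclic voltammetry (FSCV) of
evoked dopamine release in slices, and operant self-administration
behavior. Each stream is paired with a synthetic-data generator that plants
known ground truth, which is how the package tests itself. This vignette
documents the models, the tunable parameters, the numerical choices, and
the limits of what the synthetic data can show.

## Fiber photometry

### Signal model

A recording carries two channels sampled at 120 Hz (12 ksps acquisition
decimated by 100): the dopamine-dependent sensor channel excited at 465 nm
and a dopamine-independent control fluorophore at 560 nm. Both share
photobleaching and motion artifacts; only the sensor channel carries
dopamine transients. The generator's model is

* `F465(t) = B(t)·(1 + s(t)) + m(t) + ε₄₆₅(t)`
* `F560(t) = g·(B(t) + m(t)) + ε₅₆₀(t)`

with `B(t)` the bleached baseline `baseline_f·((1−φ) + φ·e^{−t/τ_b})`,
`m(t)` a smoothed Gaussian motion artifact, `g` the control gain, and
`s(t)` a sum of transient kernels. The transient kernel is a difference of
exponentials `(1 − e^{−Δt/τ_r})·e^{−Δt/τ_d}` normalised to unit peak, so a
planted amplitude `A` is the transient's actual peak ΔF/F. Transients are
planted multiplicatively on the bleached baseline, which is what makes
their ΔF/F amplitude invariant to bleach state. Both channels pass a
zero-phase second-order Butterworth low-pass at 6 Hz by default, emulating
the demodulated acquisition output; `lowpass_hz = NA` disables it for exact
closed-form tests. The recording light is duty-cycled 300 s on / 60 s off
(an 83% duty cycle); off samples stay on the time grid as `NA` with
`mask = FALSE`.

Transient amplitude and kinetics of the dopamine sensor in vivo are not
well constrained by published data; the defaults (peak 5% ΔF/F, rise
0.1 s, decay 1.0 s, rate 0.05 events/s) are order-of-magnitude placeholders
recorded in every simulation's ground truth, not measured constants.

### ΔF/F and z-scoring

Each duty-cycle block is processed independently by default, because
bleaching leaves every block with its own baseline: the control channel is
regressed onto the sensor channel (OLS; the regression direction is fixed
by the arithmetic of subtracting a fitted control *from* the sensor
signal), and

ΔF/F = (F₄₆₅ − F̂₅₆₀) / F̂₅₆₀.

"Alignment" of the channels is the affine fit itself; no time-lag
correction is applied. A whole-trace fit is available via
`per_block = FALSE`. A fitted control that is zero or negative anywhere is
an error naming the sample, never silently clipped.

Z-scoring uses the block's own mean and SD by default (`PER_BLOCK`). The
reference population is genuinely ambiguous in the field's descriptions —
standardizing globally before applying the windowed criterion is equally
defensible — so both are implemented behind `z_reference`; the detection
rule itself is invariant to affine rescaling of z, so the choice affects
only reported peak heights, not onsets.

### Transient detection

A sample is an event onset when its z value exceeds the mean plus `k` SD
(default `k = 3`) of the z scores over the immediately preceding 0.5 s,
with the window required to lie inside the same block — hence no onset can
occur within 0.5 s of a block start. The peak is the z maximum from onset
until z first returns below the window mean; that return rule is this
package's definition (interactive event-detection tools rarely publish
theirs). A 0.5 s refractory period suppresses re-triggering on a single
rising phase. The implementation uses centered cumulative sums for the
rolling moments and is tested for exact equality against a naive
per-sample re-computation.

On planted transients at the default settings the detector's recall
exceeds 0.9. Its *precision* is intrinsically poor (~0.25 at the default
planted rate of 3 events/min): a per-sample mean + 3 SD rule crosses
threshold on noise alone at roughly 0.002 per sample for near-Gaussian
noise — about 0.2 false onsets per second at 120 Hz, orders of magnitude
above what a 0.05 Hz true-event rate can dilute. This is a property of the
rule, not of the implementation: practical use of such thresholds relies
on additional curation (amplitude/shape screens, manual review) that the
rule itself does not encode. Users comparing epochs should note that the
false-positive rate is stationary, so it cancels in *differences* of rates
but inflates both terms of a ratio toward 1.

### Epoch frequencies

`transient_frequency()` divides onset counts by recorded minutes only —
one 5-on/1-off cycle containing 5 events is 1.0 events/min, not 0.83.
Ratios against a zero baseline rate are flagged undefined rather than
returned as infinity.

## FSCV

Evoked responses are analyzed as extracted oxidation-current or
concentration time series sampled at 10 Hz (one voltammetric scan per
100 ms); voltammogram-level processing is out of scope. Calibration is a
least-squares line over standards spanning 0.1–2 µM; conversion inverts
the line per sample and flags (never clips) values outside the calibrated
range. A non-positive calibration slope is rejected as an electrode fault.

Peak amplitude is measured above a 1 s pre-stimulus baseline — long enough
to average noise, much shorter than the 2 min inter-stimulus interval used
in slice protocols. The reuptake constant τ comes from nonlinear least
squares (Levenberg–Marquardt, via `minpack.lm`) of
`C(t) = b + A·e^{−(t−t_peak)/τ}` over the window from the peak to the
first sample at or below `b + 0.1·A` (configurable `fit_fraction`; the
window rule is declared here, as published analyses rarely state theirs).
Start values are `A₀` from the observed peak, `τ₀` from the time to
half-peak divided by ln 2, `b₀` from the pre-stimulus mean. An amplitude
at or below three pre-stimulus SDs is refused as degenerate rather than
fitted. On the simulation grid τ ∈ {0.3, 0.6, 1.2} s at default noise
(0.02 µM on a 1 µM peak), the median relative error of τ̂ is 4–6%.

The simulator's evoked kernel rises linearly over `rise_time_s` (default
0.3 s) and decays exponentially, so the noiseless peak equals
baseline + peak exactly and the decay obeys the closed form used in tests.
Five-pulse 100 Hz trains superpose per-pulse kernels.

## Operant schedules

The schedule semantics are: every reinforced response starts a 5 s cue and
a 10 s timeout simultaneously (one 10 s lockout — the wording "cue for 5 s
and a 10 s timeout" is treated as overlapping, not sequential); responses
during timeouts and intertrial periods are counted but never reinforced;
FR1 and PR sessions end early at the 64-reinforcer overdose cap. In
multiple-dose sessions (one 30 min trial per dose, descending
1.0 → 0 mg/kg after a 0.5 mg/kg training trial, 1 min intertrial timeouts)
the cap is applied within each dose trial, because a session-level cap
would truncate the paradigm after two trials while published dose-response
curves report all seven.

The PR requirement for reinforcer `n` is `round(5·(e^{0.18·n} − 1))` with
half-away-from-zero rounding, floored at 1 — the rounding convention is
chosen because it reproduces the published requirement series exactly for
n = 1..17. Printed versions of that series often begin "1, 1"; the formula
yields a single 1, and the duplicate (a free first reinforcer) is left to
the caller. Breakpoint is the requirement of the last infusion before the
first ≥1 h infusion-free interval; a terminal interval shorter than 1 h
does not truncate, and zero infusions give breakpoint 0 (a case published
definitions never address).

Infusion durations scale proportionally with dose, anchored at
(1.0 mg/kg, 7.07 s) and rounded to 2 decimals half away from zero, which
reproduces the published duration set 7.07/1.77/0.88/0.44/0.22/0 s. (The
0.5 mg/kg training-dose duration is printed as 3.53 s in some protocols;
proportional scaling with this rounding gives 3.54 s — the discrepancy is
one unit in the last decimal under a different rounding convention.)

The "20% variability" comparator used in acquisition and stability rules
is `|a − b| / mean(a, b)`; field descriptions never define the
denominator, so it is documented and configurable. An active/inactive
ratio with zero inactive responses passes the >2:1 test (treated as
infinite discrimination). The sucrose acquisition variant requires its
4-day run to include the final training day.

### The agent model

The simulator's responder is deliberately minimal: Poisson (or exactly
regular) active pokes, independent Poisson inactive pokes, a
post-infusion satiety pause proportional to the delivered dose, and a PR
quit probability `1 − (1 − h)^N` before each requirement `N`. It exists to
exercise schedule analytics with known event streams — the dose-scaled
pause produces the descending limb of a dose-response curve, but the model
has no extinction mechanism, so it does not reproduce the ascending limb
of the inverted-U seen in real self-administration. Dose-response analysis
functions are therefore validated on constructed curves as well as on
simulated sessions.

## Numerical choices and degenerate inputs

* Rounding for published integer/decimal series is half away from zero
  throughout (`round_half_away()`); base R's round-half-even does not
  reproduce them.
* Rolling detection moments use centered cumulative sums; variance is
  floored at 0 before the square root.
* Control fits require ≥10 samples and nonzero control variance; z-scoring
  requires nonzero SD; decay fits require ≥5 window samples and an
  amplitude above the noise floor. All are errors, not warnings.
* Every generator takes one integer seed and restores the caller's RNG
  state; identical seeds give bit-identical outputs.
* Event-log times are seconds from session start, 0-based; logs written to
  CSV round-trip exactly through the package's readers.

## Problem sizes used in the test suite

The shipped tests run the detector against its brute-force oracle on 100
random 10 000-sample traces, recover τ over 100 seeds per level, score
transient recovery on three 24 min recordings (~1200 s recorded time
each), and compare breakpoints against a brute-force gap scan on 1000
random PR logs — sizes chosen so the whole suite completes in well under a
minute per property while still estimating the stochastic quantities
stably.

## Known limitations

* The synthetic photometry noise is (filtered) Gaussian; real recordings
  show non-Gaussian artifacts (cable torsion, LED drift) that the control
  regression may not fully remove. Passing tests show the pipeline's
  arithmetic is right, not that the control model suffices for any given
  rig.
* Precision of the windowed threshold detector is bounded by the rule
  itself (see above); treat absolute transient rates as
  detector-referenced quantities.
* The agent model does not reproduce full inverted-U dose-response
  behavior, pharmacokinetics, or within-session satiation dynamics.
* FSCV fitting assumes a single-exponential decay; multi-component
  reuptake or diffusional distortion will bias τ̂ toward the slower
  component.
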