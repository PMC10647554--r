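---
title: "Threshold-based walking-bout detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-based walking-bout detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitbouts)
```

## The problem

Lower-back accelerometry is the workhorse of free-living mobility
monitoring, but most walking-bout detectors are tuned on young adults
walking briskly.  Slow, halting, aid-assisted gait — the norm in
long-term-care populations — produces low-amplitude, irregular
acceleration patterns that defeat cadence- and template-based methods.
This package implements a deliberately simple alternative: a staged
threshold pipeline on the 3D norm of the acceleration, which never looks at
waveform shape, only at magnitude envelopes.  That buys three properties
that matter in practice: it is cheap (linear filters and run-length logic),
it is independent of how the sensor was mounted (the 3D norm is rotation
invariant), and every decision it makes is auditable (each rejected bout is
kept with its rejection reason).

## The pipeline and its assumptions

`detect_walking()` composes eight deterministic stages; there is no
randomness anywhere in the detector.

1. **Zero-lag detrending.**  Each axis passes through a 4th-order
   Butterworth low pass at 0.25 Hz, applied forward and backward so the
   estimate has no phase delay, and the estimate is subtracted from the raw
   signal.  The assumption is that gravity and posture change live below
   0.25 Hz while gait content (fundamentals 0.5–3 Hz and harmonics) lives
   above it; the complementary gain at 2 Hz is $1 - (1 + (2/0.25)^8)^{-1}$,
   within $10^{-7}$ of unity, so gait amplitudes survive essentially
   untouched.
2. **3D magnitude** collapses the axes to one nonnegative series in g.
3. **Binarization** against the activity threshold (strictly above counts
   as active).
4. **Activity likelihood**: the binary series smoothed by a
   Gaussian-weighted moving average, valued in $[0,1]$.
5. **Gap filtering**: a gap (maximal inactive run) is genuine non-activity
   iff it contains at least `min_gap_frames` samples with likelihood below
   0.2; otherwise it is absorbed into the surrounding activity.  Gaps
   touching either end of the recording are always retained — there is no
   surrounding activity that could justify absorbing them.
6. **Transition rejection**: within each activity bout, the fraction of
   *smoothed-magnitude* samples above 0.4 g must stay below 2.5% for the
   bout to count as walking.  Sit–stand transfers produce second-scale
   pulses of 0.6–1 g; walking at everyday pace does not.
7. **Minimum duration**: walking bouts shorter than 2 s are rejected (a
   bout of exactly 2 s is kept).
8. **Output**: surviving bouts as half-open, 0-based frame intervals plus
   the equivalent per-sample label stream.  Rejected bouts stay in the
   table as `rejected_transition` / `rejected_short`.

One subtlety is worth stating: because the detrending filter is a high
pass, an isolated high-amplitude pulse acquires a rebound tail, so the
above-threshold extent of a sit–stand transfer is longer than the pulse
itself (a 1.5 s pulse typically yields a 3–4 s activity bout).  The
heuristic stage, not the duration stage, is therefore what removes
realistic transitions — which is exactly why its smoothing kernel must not
flatten them (below).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `activity_threshold_g` | 0.05 (generic) | g | minimum magnitude at which any activity can occur |
| `likelihood_threshold` | 0.2 | – | what counts as "low" activity likelihood inside a gap |
| `min_gap_frames` | 50 generic / 100 personalized | frames @100 Hz | low-likelihood samples a gap needs to survive |
| `heuristic_threshold_g` | 0.4 | g | smoothed-magnitude level typical of transfers, not walking |
| `heuristic_fraction` | 0.025 | – | tolerated fraction of a bout above the heuristic threshold |
| `min_bout_seconds` | 2 | s | shortest interval reported as walking |
| `cutoff_hz`, `filter_order` | 0.25, 4 | Hz, – | detrending low pass |
| `kernel_window_s`, `kernel_sigma_divisor` | 2, 20 | s, – | Gaussian smoothing window and window/σ ratio |

All frame-count parameters are stated at the nominal 100 Hz and rescaled by
$f_s/100$ (rounded) for other rates.  Tie-breaks are uniformly conservative
toward non-walking: binarization uses a strict ">", the heuristic keeps a
bout only if its fraction is strictly below 2.5%, and the duration stage
keeps exactly-2 s bouts.

### Choosing the smoothing kernel

The Gaussian kernel is the one genuinely open quantity in the pipeline: the
procedure requires *a* Gaussian-weighted moving average but fixes neither
window nor σ.  The choice is pinned from two sides.  The likelihood must
bridge the momentary dips through the activity threshold that occur at the
zero crossings of the gait oscillation; at the slowest gait we target
(0.8 Hz fundamental, amplitudes just above threshold) those dips last up to
about 0.1 s, so σ must not be much smaller than that.  From the other
side, the transition heuristic reads the *smoothed* magnitude, and a 1–2 s
transfer pulse of 0.6–1 g — further reduced by roughly 0.2 g of detrending
rebound — must still show more than 0.4 g after smoothing; a σ of 0.4 s
flattens such a pulse to ~0.30 g and silently disables the heuristic
altogether, and even 0.2 s leaves a 0.8 g pulse at 0.39 g.  σ = 0.1 s
(window 2 s, `kernel_sigma_divisor = 20`) satisfies both constraints with
margin and is the default.  Both numbers are exposed in
`detector_config()` for sensitivity analyses.

## Personalized calibration

`personal_threshold()` takes the median of the *detrended* 3D magnitude
over a day of free-living wear.  The rationale: a wearer is stationary far
more often than moving, so the daily median tracks the no-movement baseline
of that person and sensor.  The median is taken on the detrended magnitude
— the same signal the threshold is later applied to; a raw-magnitude median
would sit near 1 g (gravity) and be useless as an activity threshold.  For
a stationary baseline with per-axis Gaussian noise of sd σ the detrended
magnitude is χ-distributed with 3 d.f., so the expected threshold is
$\sigma\sqrt{Q_{\chi^2_3}(0.5)} \approx 1.538\,\sigma$; sparse activity
(≤ 5% of the day) barely moves this median, which is what makes the
statistic robust.  Days are wear-time relative (`choose_calibration_day()`
slices hours $[24d, 24(d+1))$ since recording start, not calendar
midnights), matching how multi-day deployments are reasoned about.  If
calibration fails its sanity checks (under 20 h of data, or a median
outside (0, 0.5) g), `personalized_config(fallback = TRUE)` warns and
returns the generic configuration — a failed calibration must never
silently change semantics.

## What the simulator emulates — and what it does not

`build_scenario()` concatenates three segment kinds — stationary
gravity-plus-noise, quasi-periodic walking (two-harmonic sinusoid with
random-walk phase jitter, optional full stops with short ramps for halting
gait), and smooth asymmetric sit–stand pulses — then adds sensor noise,
applies a fixed mounting rotation, and emits per-sample truth labels.  The
waveform is *not* a biomechanical gait model, deliberately: the detector
consumes only magnitude-envelope structure, so a two-harmonic envelope with
the right amplitude, frequency and pause statistics exercises every code
path that real gait would.  What passing tests on this substrate show is
that the staged logic implements its specification exactly (thresholds,
tie-breaks, gap arithmetic, orientation independence, determinism).  What
they cannot show is performance on real recordings: real gait has
asymmetric, wandering envelopes, soft-tissue artefacts, non-wear periods
and annotation latency, none of which are modelled.  Validation numbers on
the synthetic cohort are analogs, not estimates of field performance.

The default cohort conditions are: gait fundamentals 0.8–2.2 Hz with
amplitudes 0.12–0.28 g (clean, slow-leaning gait); sit–stand peaks
0.6–1.0 g; per-axis sensor noise 0.005–0.012 g, the noise-floor range of
the wrist/back loggers this pipeline targets.  Calibration days use a
baseline per-axis variability of 0.04–0.06 g — free-living wear carries
pervasive low-grade movement (postural adjustment, fidgeting, ambient
vibration) far above the bench noise floor — which places the personalized
threshold above the generic 0.05 g and reproduces the qualitative behaviour
seen on real wear data: the personalized variant is the more conservative
one, trading a little sensitivity for specificity.  Problem sizes are
chosen for desk-scale reproducibility: 10 participants, ~4-minute trials,
2-h calibration days (the daily-median statistic is length-invariant for a
stationary baseline), 20 seeds per noise level in the recovery study.

## Numerical choices

- **Zero-phase filtering** is forward–backward application of the 4th-order
  filter with odd-reflection padding of length 3 × (coefficient count) and
  steady-state initial conditions obtained from the companion-matrix
  solve, so a constant input passes through exactly and edge transients are
  confined to rounding error.  The recursion runs in compiled code; results
  are reproducible bit for bit.
- **Smoothing edges** truncate and renormalize the kernel rather than
  zero-pad, so a stationary edge is not dragged toward zero and a constant
  signal is reproduced exactly.
- **Degenerate inputs**: traces shorter than three pad lengths refuse to
  filter (explicit "trace too short" error); cutoffs at or above Nyquist,
  even kernel windows, kernels longer than the signal, non-finite samples,
  likelihoods outside $[0,1]$ and empty bouts all raise typed errors, each
  annotated with the pipeline stage that raised it.
- **Conventions**: frames are 0-based, intervals half-open
  $[\text{start}, \text{end})$, durations $(\text{end}-\text{start})/f_s$;
  bout sets and label streams convert to each other losslessly.
- **Undefined metrics** (zero denominators) are explicit `NA` markers,
  excluded from cohort means with a reported skip count — never silently
  zero.  Cohort standard deviations use the $n-1$ denominator.

## Known limitations

- The generic 0.05 g threshold assumes a bench-grade noise floor; per-axis
  noise above ~0.02 g makes stationary magnitude flicker across the
  threshold and the gap-absorption logic can then stitch noise into long
  spurious bouts.  Personalized calibration exists precisely to move the
  threshold above a wearer's real baseline.
- Bout boundaries inherit the detrending rebound: transfers adjacent to
  walking are usually absorbed into the walking bout, widening it by a
  second or two on each side.  Per-sample specificity, not bout counting,
  is the honest way to score this behaviour.
- The pipeline is offline by construction (zero-phase filtering and
  symmetric smoothing look into the future); streaming operation would
  need windowed re-design and re-derived thresholds.
- Step-level gait features (cadence, step time, symmetry) are out of scope:
  the output is the walking/non-walking partition only.
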