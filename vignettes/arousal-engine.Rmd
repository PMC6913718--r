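---
title: "A personal-baseline arousal classification engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A personal-baseline arousal classification engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcea)
```

Heart rate rises with emotional arousal, and people with emotion-regulation
difficulties often notice their arousal only when it is already extreme.
Ambulatory biofeedback puts a number on arousal in real time: a smartwatch
measures heart rate by photoplethysmography (PPG), and the wearer is shown
how far the current value sits from their own resting baseline. `pcea`
implements that pipeline end to end — calibration, classification, activity
gating, and the annotated timeline — as plain R functions over tibbles, with
a simulator standing in for the hardware.

## The model

### Personal baseline

Heart rate is only meaningful relative to the person wearing the sensor, so
everything starts from a **baseline measurement**: valid samples (sensor
accuracy code at least `min_accuracy`, default 1 on the −1…3 scale, where −1
means no skin contact and 3 most accurate) are accumulated until a preset
count is reached — 300 by default, roughly five minutes at the 1 Hz cadence
of a wrist sensor. The baseline is the arithmetic mean μ of those samples
and their sample standard deviation σ (the *n*−1 estimator, the standard
choice for estimating a person's dispersion from a sample; the accumulator
keeps Welford moments, so the result depends only on the accepted multiset).
σ is floored at `sd_floor_bpm` (default 1 bpm) so the level bands below stay
well defined when the calibration window happens to be nearly constant. Both
values can be manually overridden — useful when the calibration period was
unrepresentative — and the result is flagged as such. No outlier rejection
is applied beyond the accuracy filter: a high reading during calibration is
information about the person, not an artifact, unless the sensor itself says
otherwise.

### Ten arousal levels

With deviation $d = \mathrm{HR} - \mu$ and step size $k = m\sigma$, the
classified level is

$$ L = \operatorname{sign}(d)\cdot\min\!\bigl(5,\ \lfloor |d|/k \rfloor + 1\bigr), $$

ten values in $\{-5,\dots,-1, 1,\dots,5\}$: below-baseline states mirror the
above-baseline ones and there is no level 0. The sensitivity multiplier $m$
is a user setting: 1.0 SD per level (`normal`), 1.5 (`low`, fewer level
changes), 0.5 (`high`, more). Two conventions are ours because no edge rule
is inherent in the formula:

* **Half-open bands.** A deviation of exactly $k$ lands in the *next* band
  (level 2), i.e. bands are $[0,k), [k,2k), \dots$. Any consistent rule
  would do; half-open intervals make `findInterval`-style reasoning and the
  bisection diagnostics exact.
* **Sign of zero.** $d = 0$ maps to $+1$. A dashboard must always show a
  level, so the tie must break one way; we chose the positive side. A calm
  wearer whose current heart rate straddles the calibrated mean would
  otherwise flip between $+1$ and $-1$ — those flips are real level changes
  under this model, which is worth remembering when choosing a baseline
  (see the fixtures note below).

### Periodic evaluation

New data are compared with old every `eval_period_s` seconds (default 10).
Each evaluation takes the quality-filtered samples in the half-open window
$(\text{last eval}, \text{now}]$, averages them into a representative heart
rate, and classifies. A window with no valid sample carries the previous
level forward silently — a sensor losing contact should not manufacture
changes. The first window is anchored 1 ms before the first sample so that
sample is included, and the final, possibly partial, window is evaluated
like any other, so every sample is seen exactly once. A window mean (rather
than the latest instantaneous reading) was chosen as the representative
value because it is robust to single-beat PPG noise; this is a design
choice, not a property of the formula. No hysteresis or debouncing is
applied: every level change at an evaluation tick is an event, and any
smoothing belongs in the notification policy, not the detector.

### Activity gating and notifications

A heart-rate rise from climbing stairs is not emotional arousal. The engine
classifies each window's physical activity from the accelerometer with a
transparent threshold rule standing in for the opaque recognisers wearable
platforms ship: the mean absolute dynamic acceleration
$\overline{\lvert\,\lVert a\rVert - g\,\rvert}$ (g = 9.81 m/s²) is
`stationary` below `activity_t1` (default 0.5 m/s²), `light` in
$[t_1, t_2)$, `vigorous` at or above `activity_t2` (default 3.0 m/s²); an
empty window is stationary. When a change's activity is in
`gated_activities` (default: vigorous) **no notification is emitted, but
the change is still recorded** — the record stream is invariant to the
gating configuration, a property the test suite checks exhaustively.
Ungated changes produce a haptic (vibration) event, and changes at
`prompt_level` (default 4) or above additionally produce the user's
configured textual prompt, inviting reflection in the moment. Prompts fire
only on positive levels: deep below-baseline states are displayed but were
never part of the prompting behaviour; the threshold is configurable if a
use case needs otherwise.

### Timeline, notes, diary

Every change is appended to a chronological timeline with an empty,
editable note; the dashboard summary shows the status, the last three
changes, and a level-occupancy histogram whose counts necessarily sum to
the record count. A diary — timestamped free text with an optional emoticon
tag — lives alongside but independent of the change records. All of it
round-trips losslessly through RFC-4180 CSV or JSON-lines files.

## The simulator

`simulate_stream()` emulates what the wearable would have produced:

$$ \mathrm{HR}_t = \mu + \phi\,(\mathrm{HR}_{t-1} - \mu) + \text{offset}(t) + \varepsilon_t, $$

an AR(1) process (default $\phi = 0.95$ at 1 Hz — the simplest
autocorrelated stand-in for the slow wander of resting heart rate) whose
innovation SD is scaled by $\sqrt{1-\phi^2}$ so the stationary SD of the
undisturbed process equals `sigma_hr`. Scripted arousal episodes add a step
or linear-ramp offset in bpm; movement epochs add a heart-rate elevation
(+10 bpm light, +35 bpm vigorous — typical magnitudes for walking and
exercise) and drive the accelerometer's dynamic amplitude to 0.08, 1.5, or
6.0 m/s², values placed inside the detector's default bands so ground-truth
activity is recoverable. Dropout marks a sample with accuracy −1 or 0 while
still carrying a heart-rate value, mirroring how a badly-coupled PPG sensor
reports numbers the accuracy code disowns. All randomness flows from the
single `seed`, so a fixed spec reproduces its stream bit for bit.

What the simulator does **not** model: RR-interval/HRV structure, motion
artifacts that corrupt the *value* rather than the accuracy code,
circadian drift, or posture effects. Tests passing on simulated streams
therefore validate the *engine logic* — windowing, filtering, banding,
gating, record-keeping — not the field accuracy of wrist PPG.

### Fixtures

Four canonical scenarios (`make_fixture()`) are generated, not stored:
`calm_day`, `ramp`, `exercise`, `noisy`. Each ships with the baseline it is
meant to be classified against. In `calm_day` the session mean sits ~3 bpm
above the calibrated baseline mean with small within-session variability
(σ 0.8 bpm vs a baseline SD of 6): that is the realistic situation — a
baseline established earlier rarely coincides exactly with today's resting
level — and it keeps the stream inside the first positive band, so the only
event is the initial level. Centring a calm stream exactly on μ would
instead produce a stream of ±1 flips, a direct consequence of the no-level-0
convention discussed above.

## Numerical and testing choices

* Timestamps are integer milliseconds since the Unix epoch throughout (the
  Android sensor convention), held as doubles in R.
* The classifier is exercised against an independent band-enumeration
  oracle, and `run_stream()` against a naive per-window loop, on 100 seeded
  10-minute streams; both suites run in seconds.
* Calibration is checked by parameter recovery over 100 replicates:
  $|\bar x - \mu| \le 4\sigma/\sqrt{n}$ and σ̂ inside the χ² 99.99%
  interval. These bounds presuppose i.i.d. samples, so the recovery suite
  simulates with `ar_coef = 0`; under strong autocorrelation the variance
  of the mean is inflated by roughly $(1+\phi)/(1-\phi)$ and the bounds
  would not — and should not — hold.
* Problem sizes in the suite (10-minute streams, 100 replicates, 0.01-SD
  sweeps) are the smallest at which the properties are sharp; everything is
  generated at test time.

## Worked run

```{r example}
spec <- sim_spec(duration_s = 600, mu_hr = 72, sigma_hr = 6, ar_coef = 0.9,
                 dropout_rate = 0.05, seed = 7,
                 episodes = tibble::tibble(start_s = 240, end_s = 480,
                                           delta_bpm = 18, shape = "step"),
                 movement = tibble::tibble(start_s = 480, end_s = 570,
                                           intensity = "vigorous"))
sim <- simulate_stream(spec)
b <- calibrate_baseline(sim$events, engine_config())
b
run <- run_stream(sim$events, b, engine_config(), sim$accel)
glance(run)
notify_policy(run, engine_config())
```

```{r plot, fig.width = 7, fig.height = 3}
autoplot(run)
```

## Known limitations

* Heart rate is the only channel; no HRV or electrodermal input.
* Feedback is inherently delayed by up to one evaluation period plus the
  window average's inertia; the engine does not attempt to compensate.
* The activity classifier is a deliberately simple threshold rule; it will
  confuse, e.g., a bumpy car ride with exercise.
* Whether near-baseline readings should ever display −1 rather than +1 is
  a modelling convention here, not an empirical finding.
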