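# pcea

Ambulatory biofeedback apps for emotion-regulation training need a way to
tell a wearer, in the moment, how physiologically aroused they are. `pcea`
implements the computational core of such a system as a desk-testable R
package: it turns a stream of wrist-PPG heart-rate sensor events into a
signed **physiological correlate of emotional arousal (PCEA)** level,
relative to a personally calibrated baseline, with notifications gated by
physical activity and every detected change kept on an annotated timeline.
It is aimed at researchers and engineers who want to study, tune, or extend
the classification logic of such an app without smartwatch hardware: a
seedable simulator generates synthetic PPG and accelerometer streams with
known ground truth.

## The algorithm

A baseline measurement collects heart-rate samples until a preset number of
valid ones (default *n* = 300, accuracy code ≥ 1) is reached, giving a
personal mean μ and sample standard deviation σ (floored at 1 bpm); both can
be manually overridden. Streaming heart rate is then evaluated every 10 s
(configurable): the mean of the valid samples in the window, HR, is mapped
to a level

> L = sign(HR − μ) · min(5, ⌊|HR − μ| / (m·σ)⌋ + 1),

where the sensitivity multiplier m is 1.0 SD per level (*normal*), 1.5
(*low*) or 0.5 (*high*). Levels take the ten values −5…−1, 1…5; there is no
level 0 (a deviation of zero shows level 1). Every level change is recorded
together with the activity classified from the accelerometer (stationary /
light / vigorous by mean dynamic acceleration). A change triggers a haptic
notification, plus a user-defined textual prompt at level ≥ 4 — unless the
wearer is engaged in a gated activity (default: vigorous), in which case
nothing is emitted but the change is still recorded.

## Worked example

```r
library(pcea)

# 15 minutes of simulated wrist PPG: resting HR 72 +/- 6 bpm with a
# +16 bpm arousal episode between 400 s and 700 s, 5% sensor dropout.
spec <- sim_spec(duration_s = 900, mu_hr = 72, sigma_hr = 6, ar_coef = 0.9,
                 dropout_rate = 0.05, seed = 42,
                 episodes = tibble::tibble(start_s = 400, end_s = 700,
                                           delta_bpm = 16, shape = "step"))
sim <- simulate_stream(spec)

b <- calibrate_baseline(sim$events, engine_config())
b
#> <pcea_baseline> mean 71.6 bpm, SD 4.99 bpm (n = 300)

run <- run_stream(sim$events, b, engine_config(), sim$accel)
run
#> <pcea_run> 53 change event(s) over 90 evaluation window(s)
#> # A tibble: 53 x 5
#>   timestamp level prev_level hr_bpm activity
#> 1      9999     2         NA   80.3 stationary
#> 2     29999    -1          2   69.5 stationary
#> ...

tl <- record_change(empty_timeline(), run)
tl <- add_note(tl, 2, "argument on the phone")
dashboard_summary(tl)
#> == Arousal engine dashboard ==
#> Records: 53 | diary entries: 0 | current level: 3
#> Last 3 change(s):
#>   1970-01-01 00:14:59  level +3 (81.6 bpm, stationary)
#>   1970-01-01 00:14:49  level +2 (78.0 bpm, stationary)
#>   1970-01-01 00:14:29  level +1 (74.6 bpm, stationary)
#> Level occupancy:
#>   -3: 2   -2: 5   -1: 12   +1: 9   +2: 6   +3: 8   +4: 6   +5: 5
```

The calibrated baseline (71.6 ± 5.0 bpm) recovers the simulated person;
during the scripted episode the level climbs to +4/+5 (the prompt range),
and `notify_policy(run, engine_config())` lists the haptic and prompt
notifications the wearer would have received. `autoplot(run)` draws the
level trace; `tidy()`/`glance()` give broom-style summaries.

The same workflow is available from a shell:

```sh
pcea_cli=$(Rscript -e 'cat(system.file("cli","pcea",package="pcea"))')
Rscript $pcea_cli simulate  --spec spec.yaml --out session/
Rscript $pcea_cli calibrate --events session/events.csv --out session/
Rscript $pcea_cli run       --events session/events.csv --accel session/accel.csv \
                            --baseline session/baseline.json --out session/
Rscript $pcea_cli report    --timeline session/timeline.csv
```

## Package tour

| Area | Functions |
|---|---|
| Event logs | `read_event_log()`, `read_accel_log()`, `quality_filter()`, `write_timeline()`, `read_timeline()` |
| Calibration | `new_baseline_state()`, `update_baseline()`, `finalize_baseline()`, `override_baseline()`, `calibrate_baseline()` |
| Classification | `classify_level()`, `detect_activity()`, `evaluate()`, `run_stream()` |
| Timeline & feedback | `record_change()`, `add_note()`, `add_diary()`, `latest_changes()`, `notify_policy()`, `dashboard_summary()` |
| Simulation | `sim_spec()`, `simulate_stream()`, `make_fixture()` |
| Batch commands | `cmd_calibrate()`, `cmd_run()`, `cmd_report()` and the `inst/cli/pcea` script |

See `vignettes/arousal-engine.Rmd` for the model, its assumptions, and the
design decisions behind the defaults.
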