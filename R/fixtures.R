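#' Canonical test fixtures
#'
#' Writes one of four named synthetic recordings to `dir` as plain-text
#' files: `events.csv`, `accel.csv`, `truth.csv` and the paired
#' `baseline.json` against which the scenario is meant to be classified.
#' The scenarios:
#'
#' * `calm_day` -- 10 min of quiet sitting. Within-session variability
#'   (sigma 0.8 bpm) is deliberately small relative to the person's
#'   established baseline SD of 6 bpm, and the session mean sits a few bpm
#'   above the earlier-calibrated baseline mean (as it typically does), so
#'   the stream stays inside the first positive band: after the initial
#'   level is emitted no further change occurs.
#' * `ramp` -- a near-noiseless linear arousal ramp of +4 baseline SDs
#'   between 120 s and 480 s, giving a known ascending level sequence.
#' * `exercise` -- a vigorous movement epoch (180-420 s) with the
#'   accompanying heart-rate elevation, plus a light epoch; level changes
#'   are recorded throughout but notifications are gated while vigorous.
#' * `noisy` -- heavy dropout (35%) and full-scale HR noise, for stressing
#'   the quality filter and carry-forward behaviour.
#'
#' @param name Fixture name.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixture <- function(name = c("calm_day", "ramp", "exercise", "noisy"),
                         dir) {
  name <- match.arg(name)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- fixture_setup(name)
  sim <- simulate_stream(fx$spec)
  paths <- c(
    events = file.path(dir, "events.csv"),
    accel = file.path(dir, "accel.csv"),
    truth = file.path(dir, "truth.csv"),
    baseline = file.path(dir, "baseline.json")
  )
  write_event_log(sim$events, paths[["events"]])
  write_accel_log(sim$accel, paths[["accel"]])
  readr::write_csv(sim$truth, paths[["truth"]], progress = FALSE)
  write_baseline(fx$baseline, paths[["baseline"]])
  invisible(paths)
}

fixture_setup <- function(name) {
  ref <- function(mean, sd) {
    new_baseline(mean_hr = mean, sd_hr = sd, n = 300L, overridden = TRUE,
                 sd_floor = 1.0)
  }
  switch(name,
    calm_day = list(
      spec = sim_spec(duration_s = 600, mu_hr = 72, sigma_hr = 0.8,
                      ar_coef = 0.95, dropout_rate = 0.02, seed = 101L),
      baseline = ref(69, 6)
    ),
    ramp = list(
      spec = sim_spec(duration_s = 600, mu_hr = 71, sigma_hr = 0.5,
                      ar_coef = 0.5, dropout_rate = 0, seed = 202L,
                      episodes = tibble(start_s = 120, end_s = 480,
                                        delta_bpm = 24, shape = "ramp")),
      baseline = ref(70, 6)
    ),
    exercise = list(
      spec = sim_spec(duration_s = 600, mu_hr = 72, sigma_hr = 2,
                      ar_coef = 0.8, dropout_rate = 0.02, seed = 303L,
                      movement = tibble(start_s = c(180, 480),
                                        end_s = c(420, 540),
                                        intensity = c("vigorous", "light"))),
      baseline = ref(71, 6)
    ),
    noisy = list(
      spec = sim_spec(duration_s = 600, mu_hr = 72, sigma_hr = 6,
                      ar_coef = 0.95, dropout_rate = 0.35, seed = 404L),
      baseline = ref(72, 6)
    )
  )
}
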