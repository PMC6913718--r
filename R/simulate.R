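#' Specify a synthetic wrist-PPG stream
#'
#' Describes a simulated recording session: an AR(1) resting heart-rate
#' process around `mu_hr` whose stationary SD equals `sigma_hr`, overlaid
#' with scripted arousal episodes (step or ramp offsets in bpm), movement
#' epochs that elevate heart rate and accelerometer dynamics, and sensor
#' dropout marked by low accuracy codes. All randomness flows from the
#' single `seed`, so a fixed spec reproduces the stream bit for bit.
#'
#' Movement epochs raise heart rate by `hr_boost` (defaults: +10 bpm light,
#' +35 bpm vigorous) and drive the accelerometer's dynamic amplitude to
#' `accel_amp` (defaults 0.08 / 1.5 / 6.0 m/s^2), i.e. inside the default
#' stationary / light / vigorous detection bands. Dropout samples still
#' carry heart-rate values drawn from the same process -- on a real wrist
#' sensor a bad-contact reading reports a number, the accuracy code is what
#' marks it invalid.
#'
#' @param duration_s Length of the session in seconds.
#' @param sample_period_s Sampling period (default 1 s, the wearable's
#'   cadence).
#' @param mu_hr,sigma_hr Baseline heart-rate mean and stationary SD, bpm.
#' @param ar_coef AR(1) coefficient in `[0, 1)`; 0.95 at 1 Hz mimics the
#'   slow wander of resting heart rate.
#' @param episodes Arousal episodes: a data frame with columns `start_s`,
#'   `end_s`, `delta_bpm`, `shape` (`"step"` or `"ramp"`), or `NULL`.
#' @param movement Movement epochs: a data frame with columns `start_s`,
#'   `end_s`, `intensity` (`"light"` or `"vigorous"`), or `NULL`.
#' @param dropout_rate Probability that a sample is recorded with accuracy
#'   below 1 (drawn from \{-1, 0\}); clean samples get accuracy 3.
#' @param seed Integer seed for the single random generator.
#' @param start_time_ms Timestamp of the first sample.
#' @param hr_boost Named bpm offsets applied during `light`/`vigorous`
#'   movement.
#' @param accel_amp Named dynamic-acceleration amplitudes (m/s^2) per
#'   activity.
#' @param source_id Device/session label written on every event.
#' @return A validated `sim_spec` object.
#' @export
sim_spec <- function(duration_s,
                     sample_period_s = 1,
                     mu_hr = 72,
                     sigma_hr = 6,
                     ar_coef = 0.95,
                     episodes = NULL,
                     movement = NULL,
                     dropout_rate = 0.05,
                     seed = 1L,
                     start_time_ms = 0,
                     hr_boost = c(light = 10, vigorous = 35),
                     accel_amp = c(stationary = 0.08, light = 1.5, vigorous = 6.0),
                     source_id = "sim") {
  spec <- structure(
    list(duration_s = as.numeric(duration_s),
         sample_period_s = as.numeric(sample_period_s),
         mu_hr = as.numeric(mu_hr), sigma_hr = as.numeric(sigma_hr),
         ar_coef = as.numeric(ar_coef),
         episodes = normalise_epochs(episodes,
                                     c("start_s", "end_s", "delta_bpm", "shape")),
         movement = normalise_epochs(movement,
                                     c("start_s", "end_s", "intensity")),
         dropout_rate = as.numeric(dropout_rate),
         seed = as.integer(seed),
         start_time_ms = as.numeric(start_time_ms),
         hr_boost = hr_boost, accel_amp = accel_amp,
         source_id = as.character(source_id)),
    class = "sim_spec"
  )
  validate_sim_spec(spec)
}

normalise_epochs <- function(x, cols) {
  if (is.null(x)) {
    return(as_tibble(setNames(rep(list(logical(0)), length(cols)), cols)))
  }
  if (is.list(x) && !is.data.frame(x)) x <- bind_rows(lapply(x, as_tibble))
  check_event_frame(x, cols, "episodes/movement")
  as_tibble(x)[cols]
}

validate_sim_spec <- function(spec) {
  if (!isTRUE(spec$duration_s > 0) || !isTRUE(spec$sample_period_s > 0)) {
    abort("Durations and sample period must be positive.")
  }
  if (!isTRUE(spec$mu_hr > 0) || !isTRUE(spec$sigma_hr >= 0)) {
    abort("`mu_hr` must be > 0 and `sigma_hr` >= 0.")
  }
  if (!isTRUE(spec$ar_coef >= 0 && spec$ar_coef < 1)) {
    abort("`ar_coef` must lie in [0, 1).")
  }
  if (!isTRUE(spec$dropout_rate >= 0 && spec$dropout_rate <= 1)) {
    abort("`dropout_rate` must lie in [0, 1].")
  }
  if (is.na(spec$seed)) abort("`seed` must be an integer.")
  ep <- spec$episodes
  if (nrow(ep)) {
    ok <- ep$start_s >= 0 & ep$end_s > ep$start_s & ep$end_s <= spec$duration_s &
      ep$shape %in% c("step", "ramp") & is.finite(ep$delta_bpm)
    if (!all(ok)) abort("Episodes must lie within the duration with shape step/ramp.")
  }
  mv <- spec$movement
  if (nrow(mv)) {
    ok <- mv$start_s >= 0 & mv$end_s > mv$start_s & mv$end_s <= spec$duration_s &
      mv$intensity %in% c("light", "vigorous")
    if (!all(ok)) {
      abort("Movement epochs must lie within the duration with intensity light/vigorous.")
    }
  }
  if (!all(c("light", "vigorous") %in% names(spec$hr_boost)) ||
      !all(activity_labels() %in% names(spec$accel_amp))) {
    abort("`hr_boost` needs light/vigorous entries; `accel_amp` needs all three activities.")
  }
  spec
}

#' Generate a synthetic PPG + accelerometer stream
#'
#' Realises a [sim_spec()]: heart rate follows
#' `HR_t = mu + ar * (HR_{t-1} - mu) + offset(t) + eps_t` with the
#' innovation SD scaled by `sqrt(1 - ar^2)` so the no-episode process has
#' stationary SD `sigma_hr`; `offset(t)` is the scripted episode offset
#' plus the movement heart-rate boost. Accelerometer samples carry gravity
#' plus a dynamic component of the amplitude configured for the concurrent
#' activity. Dropout samples get an accuracy code drawn from \{-1, 0\},
#' clean ones accuracy 3.
#'
#' @param spec A [sim_spec()].
#' @return A `pcea_sim` list: `events` (sensor event tibble), `accel`
#'   (accelerometer tibble), `truth` (per-sample tibble with the true
#'   arousal offset in bpm and the activity label), and `spec`.
#' @examples
#' sim <- simulate_stream(sim_spec(duration_s = 60, dropout_rate = 0, seed = 42))
#' head(sim$events)
#' @export
simulate_stream <- function(spec) {
  spec <- validate_sim_spec(spec)
  n <- floor(spec$duration_s / spec$sample_period_s)
  if (n < 1) abort("Spec yields no samples.")
  t_s <- (seq_len(n) - 1) * spec$sample_period_s
  timestamp <- spec$start_time_ms + t_s * 1000

  ep_off <- numeric(n)
  for (i in seq_len(nrow(spec$episodes))) {
    e <- spec$episodes[i, ]
    idx <- t_s >= e$start_s & t_s < e$end_s
    ep_off[idx] <- ep_off[idx] + if (e$shape == "step") e$delta_bpm else
      e$delta_bpm * (t_s[idx] - e$start_s) / (e$end_s - e$start_s)
  }
  activity <- rep("stationary", n)
  for (i in seq_len(nrow(spec$movement))) {
    m <- spec$movement[i, ]
    activity[t_s >= m$start_s & t_s < m$end_s] <- m$intensity
  }
  mv_off <- numeric(n)
  mv_off[activity == "light"] <- spec$hr_boost[["light"]]
  mv_off[activity == "vigorous"] <- spec$hr_boost[["vigorous"]]

  withr::with_seed(spec$seed, {
    innov_sd <- spec$sigma_hr * sqrt(1 - spec$ar_coef^2)
    eps <- rnorm(n, 0, innov_sd)
    x0 <- rnorm(1, 0, spec$sigma_hr)
    x <- as.numeric(stats::filter(eps, spec$ar_coef, method = "recursive",
                                  init = x0))
    hr <- spec$mu_hr + x + ep_off + mv_off

    drop <- runif(n) < spec$dropout_rate
    accuracy <- rep(3L, n)
    accuracy[drop] <- sample(c(-1L, 0L), sum(drop), replace = TRUE)

    amp <- unname(spec$accel_amp[activity])
    sgn <- sample(c(-1, 1), n, replace = TRUE)
  })

  events <- tibble(timestamp = timestamp, hr_bpm = hr, accuracy = accuracy,
                   source_id = spec$source_id)
  accel <- tibble(timestamp = timestamp, ax = 0, ay = 0,
                  az = STANDARD_GRAVITY + amp * sgn)
  truth <- tibble(timestamp = timestamp, arousal_offset_bpm = ep_off,
                  activity = activity)
  structure(list(events = events, accel = accel, truth = truth, spec = spec),
            class = "pcea_sim")
}

#' @export
print.pcea_sim <- function(x, ...) {
  cat(sprintf(
    "<pcea_sim> %d samples @ %g s | mu %g bpm, sigma %g, ar %g | %d episode(s), %d movement epoch(s), dropout %.0f%%\n",
    nrow(x$events), x$spec$sample_period_s, x$spec$mu_hr, x$spec$sigma_hr,
    x$spec$ar_coef, nrow(x$spec$episodes), nrow(x$spec$movement),
    100 * x$spec$dropout_rate))
  invisible(x)
}

#' Load a simulation spec from YAML
#'
#' The YAML mirrors the [sim_spec()] arguments; `episodes` and `movement`
#' are lists of mappings with the epoch fields.
#'
#' @param path Path to a YAML file.
#' @return A `sim_spec`.
#' @export
read_sim_spec <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Spec file not found: ", path), class = "pcea_data_error")
  }
  vals <- yaml::read_yaml(path)
  for (nm in c("hr_boost", "accel_amp")) {
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  }
  unknown <- setdiff(names(vals), names(formals(sim_spec)))
  if (length(unknown)) {
    abort(paste0("Unknown sim spec fields: ", paste(unknown, collapse = ", ")),
          class = "pcea_data_error")
  }
  do.call(sim_spec, vals)
}
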