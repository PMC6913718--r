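#' Streaming engine state
#'
#' Holds everything the periodic evaluator needs between ticks: the personal
#' baseline, the configuration, the last emitted level (none before the
#' first evaluation with data) and the time of the last evaluation. Windows
#' are half-open `(last_eval_time, now]`; initialising `last_eval_time` to
#' one millisecond before the first sample makes the first window cover it.
#'
#' @param baseline A [`pcea_baseline`][finalize_baseline].
#' @param config An [engine_config()].
#' @param start_time_ms Timestamp (ms) at which evaluation starts; typically
#'   `min(events$timestamp) - 1`.
#' @return An `engine_state` object.
#' @export
engine_state <- function(baseline, config = engine_config(), start_time_ms = 0) {
  stopifnot(inherits(baseline, "pcea_baseline"))
  config <- validate_engine_config(config)
  structure(
    list(baseline = baseline, config = config,
         last_level = NA_integer_, last_eval_time = as.numeric(start_time_ms)),
    class = "engine_state"
  )
}

#' Evaluate new data against old at a tick
#'
#' One step of the periodic comparison. If less than one evaluation period
#' has elapsed since the last evaluation the state is returned unchanged.
#' Otherwise the quality-filtered heart-rate events in `(last_eval_time, now]`
#' are averaged into a representative heart rate, classified against the
#' baseline, and -- if the level differs from the last one (or no level has
#' been emitted yet) -- a change event is produced together with the
#' activity classified from the accelerometer samples in the same window.
#' A window without valid heart-rate data carries the previous level
#' forward and produces no event. `last_eval_time` advances to `now`
#' whenever a full period has elapsed.
#'
#' @param state An [engine_state()].
#' @param now Current timestamp, ms; must not precede `last_eval_time`.
#' @param events Sensor event tibble.
#' @param accel Optional accelerometer tibble; `NULL` means stationary.
#' @return A list with elements `state` (updated) and `change` (a one-row
#'   tibble `timestamp, level, prev_level, hr_bpm, activity`, or `NULL`).
#' @export
evaluate <- function(state, now, events, accel = NULL) {
  stopifnot(inherits(state, "engine_state"))
  if (now < state$last_eval_time) {
    abort("`now` precedes the last evaluation time.")
  }
  cfg <- state$config
  period_ms <- cfg$eval_period_s * 1000
  if (now - state$last_eval_time < period_ms) {
    return(list(state = state, change = NULL))
  }
  lo <- state$last_eval_time
  state$last_eval_time <- now

  win <- quality_filter(events, cfg$min_accuracy)
  win <- win[win$timestamp > lo & win$timestamp <= now & is.finite(win$hr_bpm), ,
             drop = FALSE]
  if (nrow(win) == 0L) {
    return(list(state = state, change = NULL))
  }
  rep_hr <- mean(win$hr_bpm)
  level <- classify_level(rep_hr, state$baseline, cfg$sensitivity)

  if (!is.na(state$last_level) && level == state$last_level) {
    return(list(state = state, change = NULL))
  }
  acc_win <- NULL
  if (!is.null(accel) && nrow(accel) > 0) {
    acc_win <- accel[accel$timestamp > lo & accel$timestamp <= now, , drop = FALSE]
  }
  change <- tibble(
    timestamp = now,
    level = level,
    prev_level = state$last_level,
    hr_bpm = rep_hr,
    activity = detect_activity(acc_win, cfg$activity_t1, cfg$activity_t2)
  )
  state$last_level <- level
  list(state = state, change = change)
}

#' Per-window evaluation table for a whole log
#'
#' Vectorised companion to [evaluate()]: slices the log into consecutive
#' evaluation windows from the first to the last timestamp and returns one
#' row per window with the representative (mean valid) heart rate, the
#' classified level (`NA` when the window holds no valid sample), the
#' carried-forward effective level, and the activity label. The final
#' window may be partial and is evaluated like any other, so every sample
#' in the log is seen exactly once.
#'
#' @inheritParams run_stream
#' @return A tibble `timestamp, n_events, hr_bpm, level, level_effective,
#'   activity`, one row per evaluation tick.
#' @export
evaluate_windows <- function(events, baseline, config = engine_config(),
                             accel = NULL) {
  stopifnot(inherits(baseline, "pcea_baseline"))
  config <- validate_engine_config(config)
  check_event_frame(events, event_cols, "events")
  empty <- tibble(timestamp = numeric(0), n_events = integer(0),
                  hr_bpm = numeric(0), level = integer(0),
                  level_effective = integer(0), activity = character(0))
  if (nrow(events) == 0L) return(empty)

  t0 <- min(events$timestamp)
  tN <- max(events$timestamp)
  period_ms <- config$eval_period_s * 1000
  k_max <- ceiling((tN - (t0 - 1)) / period_ms)
  if (k_max < 1) return(empty)
  ticks <- (t0 - 1) + period_ms * seq_len(k_max)

  valid <- quality_filter(events, config$min_accuracy)
  valid <- valid[is.finite(valid$hr_bpm), , drop = FALSE]
  vwin <- floor((valid$timestamp - t0) / period_ms) + 1L  # 1-based window id
  keep <- vwin >= 1L & vwin <= k_max
  hr_by_win <- valid$hr_bpm[keep]
  id <- vwin[keep]
  agg <- tibble(win = id, hr = hr_by_win) |>
    group_by(.data$win) |>
    summarise(n_events = dplyr::n(), hr_bpm = mean(.data$hr), .groups = "drop")

  out <- tibble(win = seq_len(k_max), timestamp = ticks) |>
    left_join(agg, by = "win")
  out$n_events[is.na(out$n_events)] <- 0L

  out$activity <- "stationary"
  if (!is.null(accel) && nrow(accel) > 0) {
    check_event_frame(accel, accel_cols, "accel")
    awin <- floor((accel$timestamp - t0) / period_ms) + 1L
    akeep <- awin >= 1L & awin <= k_max
    aagg <- tibble(win = awin[akeep],
                   dev = abs(sqrt(accel$ax[akeep]^2 + accel$ay[akeep]^2 +
                                    accel$az[akeep]^2) - STANDARD_GRAVITY)) |>
      group_by(.data$win) |>
      summarise(dyn = mean(.data$dev), .groups = "drop")
    idx <- match(aagg$win, out$win)
    out$activity[idx] <- activity_from_dyn(aagg$dyn, config$activity_t1,
                                           config$activity_t2)
  }

  out$level <- NA_integer_
  has_hr <- !is.na(out$hr_bpm)
  if (any(has_hr)) {
    out$level[has_hr] <- classify_level(out$hr_bpm[has_hr], baseline,
                                        config$sensitivity)
  }
  out$level_effective <- out$level
  out <- tidyr::fill(out, "level_effective", .direction = "down")
  out[, c("timestamp", "n_events", "hr_bpm", "level", "level_effective",
          "activity")]
}

#' Replay a whole event log through the engine
#'
#' Batch driver equivalent to calling [evaluate()] at every evaluation-period
#' boundary from the first to the last event timestamp: deterministic for a
#' fixed log, baseline and configuration. Returns the sequence of detected
#' level changes; the first window with valid data always emits the initial
#' level.
#'
#' @param events Sensor event tibble (time-ordered; see [read_event_log()]).
#' @param baseline A [`pcea_baseline`][finalize_baseline].
#' @param config An [engine_config()].
#' @param accel Optional accelerometer tibble for activity classification.
#' @return A `pcea_run` tibble of change events: `timestamp, level,
#'   prev_level, hr_bpm, activity`, with the per-window table, config and
#'   baseline attached as attributes.
#' @examples
#' sim <- simulate_stream(sim_spec(duration_s = 120, seed = 7))
#' b <- override_baseline(calibrate_baseline(sim$events,
#'        engine_config(baseline_n = 100)), 72, 6)
#' run_stream(sim$events, b, accel = sim$accel)
#' @export
run_stream <- function(events, baseline, config = engine_config(), accel = NULL) {
  win <- evaluate_windows(events, baseline, config, accel)
  has <- which(!is.na(win$level))
  changes <- tibble(timestamp = numeric(0), level = integer(0),
                    prev_level = integer(0), hr_bpm = numeric(0),
                    activity = character(0))
  if (length(has) > 0) {
    lv <- win$level[has]
    prev <- c(NA_integer_, lv[-length(lv)])
    emit <- is.na(prev) | lv != prev
    changes <- tibble(
      timestamp = win$timestamp[has][emit],
      level = lv[emit],
      prev_level = prev[emit],
      hr_bpm = win$hr_bpm[has][emit],
      activity = win$activity[has][emit]
    )
  }
  structure(changes,
            class = c("pcea_run", class(changes)),
            windows = win, config = config, baseline = baseline)
}

#' @export
print.pcea_run <- function(x, ...) {
  win <- attr(x, "windows")
  cat(sprintf("<pcea_run> %d change event(s) over %d evaluation window(s)\n",
              nrow(x), if (is.null(win)) NA_integer_ else nrow(win)))
  NextMethod()
}
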