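#' Start a baseline measurement
#'
#' A baseline measurement accumulates valid heart-rate samples until a preset
#' count (default 300) is reached, then yields the person's mean heart rate
#' and its standard deviation. State is held as streaming (Welford) moments,
#' so the finalized values depend only on the multiset of accepted samples.
#'
#' @param target_n Required number of valid samples.
#' @return A `baseline_state` object with `n_valid = 0`.
#' @seealso [update_baseline()], [finalize_baseline()]
#' @export
new_baseline_state <- function(target_n = 300) {
  target_n <- as.integer(target_n)
  if (is.na(target_n) || target_n < 2L) abort("`target_n` must be at least 2.")
  structure(
    list(n_valid = 0L, mean = 0, m2 = 0, target_n = target_n),
    class = "baseline_state"
  )
}

#' @rdname new_baseline_state
#' @param state A `baseline_state`.
#' @export
baseline_complete <- function(state) {
  stopifnot(inherits(state, "baseline_state"))
  state$n_valid >= state$target_n
}

#' Feed sensor events into a baseline measurement
#'
#' `update_baseline()` consumes one sensor event: if its accuracy code is at
#' least `min_accuracy` the sample is accepted and the running moments
#' update; otherwise the state is returned unchanged. Updating an already
#' complete state is an error -- accumulation stops at exactly `target_n`
#' accepted samples, however many rejected samples are interleaved.
#' `accumulate_baseline()` folds a whole event log, stopping silently once
#' the target is reached.
#'
#' @param state A `baseline_state`.
#' @param event A single sensor event: a one-row data frame or named list
#'   with `hr_bpm` and `accuracy`.
#' @param min_accuracy Minimum accuracy code for a sample to count as valid.
#' @return The updated `baseline_state`.
#' @export
update_baseline <- function(state, event, min_accuracy = 1) {
  stopifnot(inherits(state, "baseline_state"))
  if (baseline_complete(state)) {
    abort("Baseline measurement already complete; start a new one to recalibrate.")
  }
  acc <- as.integer(event[["accuracy"]])
  hr <- as.numeric(event[["hr_bpm"]])
  if (length(acc) != 1L || length(hr) != 1L) {
    abort("`event` must be a single sensor event.")
  }
  if (is.na(acc) || acc < min_accuracy) {
    return(state)
  }
  if (!is.finite(hr) || hr <= 0) {
    abort("Accepted events must carry a positive finite hr_bpm.")
  }
  n1 <- state$n_valid + 1L
  delta <- hr - state$mean
  mean1 <- state$mean + delta / n1
  state$m2 <- state$m2 + delta * (hr - mean1)
  state$mean <- mean1
  state$n_valid <- n1
  state
}

#' @rdname update_baseline
#' @param events Sensor event tibble (see [read_event_log()]).
#' @export
accumulate_baseline <- function(state, events, min_accuracy = 1) {
  check_event_frame(events, c("hr_bpm", "accuracy"), "events")
  for (i in seq_len(nrow(events))) {
    if (baseline_complete(state)) break
    state <- update_baseline(state, events[i, ], min_accuracy)
  }
  state
}

#' Finalize a completed baseline measurement
#'
#' Turns accumulated moments into a personal baseline: the arithmetic mean of
#' the accepted heart rates and their sample standard deviation (n-1
#' denominator), the latter raised to `sd_floor` if smaller so that level
#' bands never collapse.
#'
#' @inheritParams update_baseline
#' @param sd_floor Minimum SD in beats/min (> 0).
#' @return A `pcea_baseline` object: `mean_hr`, `sd_hr`, `n`, `overridden`,
#'   `sd_floor`.
#' @export
finalize_baseline <- function(state, sd_floor = 1.0) {
  stopifnot(inherits(state, "baseline_state"))
  if (!isTRUE(sd_floor > 0)) abort("`sd_floor` must be > 0.")
  if (!baseline_complete(state)) {
    abort(paste0("Baseline incomplete: ", state$n_valid, " of ", state$target_n,
                 " valid samples collected (", state$target_n - state$n_valid,
                 " more needed)."),
          class = "pcea_data_error")
  }
  s <- sqrt(state$m2 / (state$n_valid - 1L))
  new_baseline(mean_hr = state$mean, sd_hr = max(s, sd_floor),
               n = state$n_valid, overridden = FALSE, sd_floor = sd_floor)
}

new_baseline <- function(mean_hr, sd_hr, n, overridden, sd_floor) {
  if (!isTRUE(mean_hr > 0)) abort("Baseline mean heart rate must be > 0.")
  if (!isTRUE(sd_hr >= sd_floor)) {
    abort(paste0("Baseline SD must be at least the floor (", sd_floor, " bpm)."))
  }
  structure(
    list(mean_hr = as.numeric(mean_hr), sd_hr = as.numeric(sd_hr),
         n = as.integer(n), overridden = isTRUE(overridden),
         sd_floor = as.numeric(sd_floor)),
    class = "pcea_baseline"
  )
}

#' Manually override a baseline
#'
#' Replaces the measured mean and SD with supplied values -- the escape hatch
#' for when the calibration window was unrepresentative of the wearer. The
#' sample count is preserved and the result is marked `overridden`.
#'
#' @param baseline A `pcea_baseline`.
#' @param mean_hr,sd_hr Replacement values in beats/min; `sd_hr` must be at
#'   least the baseline's SD floor.
#' @return A `pcea_baseline` with `overridden = TRUE`.
#' @export
override_baseline <- function(baseline, mean_hr, sd_hr) {
  stopifnot(inherits(baseline, "pcea_baseline"))
  if (!isTRUE(mean_hr > 0)) abort("Override mean heart rate must be > 0.")
  if (!isTRUE(sd_hr >= baseline$sd_floor)) {
    abort(paste0("Override SD must be at least the floor (",
                 baseline$sd_floor, " bpm)."))
  }
  new_baseline(mean_hr, sd_hr, baseline$n, TRUE, baseline$sd_floor)
}

#' Calibrate a baseline from an event log in one call
#'
#' Convenience wrapper: accumulates the first `config$baseline_n` valid
#' samples of `events` (accuracy >= `config$min_accuracy`) and finalizes.
#' Errors if the log holds too few valid samples, reporting the shortfall.
#'
#' @param events Sensor event tibble.
#' @param config An [engine_config()].
#' @return A `pcea_baseline`.
#' @export
calibrate_baseline <- function(events, config = engine_config()) {
  config <- validate_engine_config(config)
  check_event_frame(events, c("hr_bpm", "accuracy"), "events")
  valid <- events$accuracy >= config$min_accuracy & is.finite(events$hr_bpm)
  hr <- events$hr_bpm[which(valid)]
  if (length(hr) < config$baseline_n) {
    abort(paste0("Insufficient valid samples for calibration: have ",
                 length(hr), ", need ", config$baseline_n, " (",
                 config$baseline_n - length(hr), " missing)."),
          class = "pcea_data_error")
  }
  hr <- hr[seq_len(config$baseline_n)]
  new_baseline(mean_hr = mean(hr), sd_hr = max(sd(hr), config$sd_floor_bpm),
               n = config$baseline_n, overridden = FALSE,
               sd_floor = config$sd_floor_bpm)
}

#' Persist a baseline as JSON
#'
#' @param baseline A `pcea_baseline`.
#' @param path File path (conventionally `baseline.json`).
#' @return `path` invisibly; `read_baseline()` returns the `pcea_baseline`.
#' @export
write_baseline <- function(baseline, path) {
  stopifnot(inherits(baseline, "pcea_baseline"))
  jsonlite::write_json(unclass(baseline), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Baseline file not found: ", path), class = "pcea_data_error")
  }
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("mean_hr", "sd_hr", "n", "overridden", "sd_floor")
  missing <- setdiff(need, names(vals))
  if (length(missing)) {
    abort(paste0(path, " lacks baseline field(s): ",
                 paste(missing, collapse = ", ")), class = "pcea_data_error")
  }
  new_baseline(vals$mean_hr, vals$sd_hr, vals$n, vals$overridden, vals$sd_floor)
}

#' @export
print.pcea_baseline <- function(x, ...) {
  cat(sprintf("<pcea_baseline> mean %.1f bpm, SD %.2f bpm (n = %d%s)\n",
              x$mean_hr, x$sd_hr, x$n,
              if (x$overridden) ", manually overridden" else ""))
  invisible(x)
}

#' @export
print.baseline_state <- function(x, ...) {
  cat(sprintf("<baseline_state> %d / %d valid samples%s\n",
              x$n_valid, x$target_n,
              if (baseline_complete(x)) " (complete)" else ""))
  invisible(x)
}
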