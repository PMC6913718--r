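# Independent oracles and small builders shared across tests.
# These deliberately avoid the package's own code paths: the classifier
# oracle enumerates band edges with findInterval, and the stream oracle is a
# naive per-window loop.

`%||%` <- function(a, b) if (is.null(a)) b else a

ref_baseline <- function(mean = 70, sd = 5, floor = 1) {
  b <- pcea::finalize_baseline(
    pcea::accumulate_baseline(
      pcea::new_baseline_state(2),
      tibble::tibble(hr_bpm = c(mean, mean), accuracy = 3L)),
    sd_floor = floor)
  pcea::override_baseline(b, mean, max(sd, floor))
}

make_events <- function(timestamp, hr_bpm, accuracy = 3L, source_id = "test") {
  tibble::tibble(timestamp = as.numeric(timestamp),
                 hr_bpm = as.numeric(hr_bpm),
                 accuracy = as.integer(accuracy),
                 source_id = source_id)
}

# Band-enumeration classifier oracle: positive deviations fall in bands
# [0,k), [k,2k), ... counted with findInterval; negative side mirrored.
oracle_level <- function(hr, mean, sd, multiplier) {
  k <- multiplier * sd
  vapply(hr, function(h) {
    d <- h - mean
    mag <- min(5L, findInterval(abs(d), k * 0:4))
    if (d >= 0) mag else -mag
  }, integer(1))
}

# Naive per-window replay of the engine: explicit loop over evaluation
# ticks, window (prev, tick], mean of valid samples, carry forward on empty.
oracle_run <- function(events, accel, mean, sd, multiplier, period_s = 10,
                       min_accuracy = 1, t1 = 0.5, t2 = 3.0) {
  if (nrow(events) == 0) return(data.frame())
  t0 <- min(events$timestamp)
  tN <- max(events$timestamp)
  p <- period_s * 1000
  out <- list()
  last_level <- NA_integer_
  lo <- t0 - 1
  tick <- lo + p
  while (lo < tN) {
    sel <- events$timestamp > lo & events$timestamp <= tick &
      !is.na(events$accuracy) & events$accuracy >= min_accuracy &
      is.finite(events$hr_bpm)
    if (any(sel)) {
      rep_hr <- mean(events$hr_bpm[sel])
      lvl <- oracle_level(rep_hr, mean, sd, multiplier)
      if (is.na(last_level) || lvl != last_level) {
        act <- "stationary"
        if (!is.null(accel)) {
          asel <- accel$timestamp > lo & accel$timestamp <= tick
          if (any(asel)) {
            dyn <- mean(abs(sqrt(accel$ax[asel]^2 + accel$ay[asel]^2 +
                                   accel$az[asel]^2) - 9.81))
            act <- if (dyn >= t2) "vigorous" else if (dyn >= t1) "light"
                   else "stationary"
          }
        }
        out[[length(out) + 1]] <- data.frame(
          timestamp = tick, level = lvl, prev_level = last_level,
          hr_bpm = rep_hr, activity = act)
        last_level <- lvl
      }
    }
    lo <- tick
    tick <- tick + p
  }
  do.call(rbind, out)
}
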