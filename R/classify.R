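#' Sensitivity settings
#'
#' The sensitivity setting controls how many baseline SDs of heart-rate
#' deviation make up one arousal level step: `normal` = 1 SD per level,
#' `low` = 1.5 SD (fewer level changes), `high` = 0.5 SD (more).
#'
#' @return A named numeric vector of SD-per-level multipliers.
#' @export
sensitivity_multipliers <- function() {
  c(low = 1.5, normal = 1.0, high = 0.5)
}

#' @rdname sensitivity_multipliers
#' @param sensitivity `"low"`, `"normal"` or `"high"`.
#' @export
sensitivity_multiplier <- function(sensitivity) {
  m <- sensitivity_multipliers()
  if (length(sensitivity) != 1L || !sensitivity %in% names(m)) {
    abort("`sensitivity` must be one of 'low', 'normal', 'high'.")
  }
  unname(m[[sensitivity]])
}

#' Activity labels recognised by the engine
#' @return `c("stationary", "light", "vigorous")`.
#' @export
activity_labels <- function() c("stationary", "light", "vigorous")

#' Classify heart rate into a signed arousal level
#'
#' Maps a heart rate onto one of ten levels, -5..-1 below the personal
#' baseline and 1..5 above; there is no level 0. With deviation
#' `d = hr - mean_hr` and step size `k = multiplier * sd_hr`, the level
#' magnitude is `min(5, floor(|d|/k) + 1)` and the sign follows `d`, with
#' `d = 0` mapping to +1 (a level is always shown). Bands are half-open: a
#' deviation of exactly `k` lands in the next band (level 2). The function
#' is vectorised over `hr`.
#'
#' @param hr Heart rate(s), beats/min; must be finite.
#' @param baseline A finalized or overridden [`pcea_baseline`][finalize_baseline].
#' @param sensitivity `"low"`, `"normal"` or `"high"`.
#' @return Integer vector of levels in \{-5..-1, 1..5\}.
#' @examples
#' b <- override_baseline(
#'   finalize_baseline(accumulate_baseline(
#'     new_baseline_state(2),
#'     tibble::tibble(hr_bpm = c(70, 70), accuracy = 3L))),
#'   mean_hr = 70, sd_hr = 5)
#' classify_level(c(70, 82.5, 110, 57.5), b)       # 1  3  5 -3
#' classify_level(75, b, sensitivity = "high")     # 3
#' @export
classify_level <- function(hr, baseline, sensitivity = "normal") {
  stopifnot(inherits(baseline, "pcea_baseline"))
  if (length(hr) == 0L) return(integer(0))
  if (any(!is.finite(hr))) abort("`hr` must be finite.")
  k <- sensitivity_multiplier(sensitivity) * baseline$sd_hr
  d <- hr - baseline$mean_hr
  band <- pmin(5, floor(abs(d) / k) + 1)
  as.integer(ifelse(d >= 0, band, -band))
}

#' Classify physical activity from an accelerometer window
#'
#' A transparent threshold classifier standing in for the wearable
#' platform's opaque activity recogniser: the mean absolute dynamic
#' acceleration, `mean(| |a| - g |)` with g = 9.81 m/s^2, is compared
#' against two thresholds. Below `t1` the window is `stationary`, in
#' `[t1, t2)` it is `light`, at or above `t2` `vigorous`. An empty window is
#' `stationary`.
#'
#' @param accel Accelerometer tibble with columns `ax`, `ay`, `az` (m/s^2);
#'   may have zero rows.
#' @param t1,t2 Thresholds in m/s^2 mean dynamic acceleration, `0 <= t1 < t2`.
#' @return One of `"stationary"`, `"light"`, `"vigorous"`.
#' @export
detect_activity <- function(accel, t1 = 0.5, t2 = 3.0) {
  if (!isTRUE(t1 >= 0 && t1 < t2)) abort("Need 0 <= t1 < t2.")
  if (is.null(accel) || nrow(accel) == 0L) return("stationary")
  check_event_frame(accel, c("ax", "ay", "az"), "accel")
  dyn <- mean(abs(sqrt(accel$ax^2 + accel$ay^2 + accel$az^2) - STANDARD_GRAVITY))
  activity_from_dyn(dyn, t1, t2)
}

STANDARD_GRAVITY <- 9.81

activity_from_dyn <- function(dyn, t1, t2) {
  out <- rep("stationary", length(dyn))
  out[dyn >= t1] <- "light"
  out[dyn >= t2] <- "vigorous"
  out[is.na(dyn)] <- "stationary"
  out
}
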