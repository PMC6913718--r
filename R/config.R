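#' Engine configuration
#'
#' Bundles every tunable of the classification engine. Defaults reproduce the
#' deployed app's standard settings: evaluate every 10 s, calibrate on 300
#' valid samples, keep readings with accuracy code 1 or higher, one baseline
#' SD per level step, prompt at level 4, and suppress notifications while the
#' wearer is in vigorous motion.
#'
#' @param eval_period_s Seconds between evaluations of new against old data.
#' @param baseline_n Number of valid heart-rate samples required to complete
#'   a baseline measurement.
#' @param min_accuracy Minimum sensor accuracy code (-1..3) for a reading to
#'   count, both during calibration and streaming classification.
#' @param sensitivity One of `"normal"` (1 SD per level), `"low"` (1.5 SD) or
#'   `"high"` (0.5 SD).
#' @param sd_floor_bpm Lower bound on the baseline SD in beats/min, so level
#'   bands stay well defined when measured variance is degenerate.
#' @param prompt_level Positive level at or above which a textual prompt is
#'   emitted in addition to the haptic notification.
#' @param prompt_message Text of the prompt; user-definable.
#' @param gated_activities Activity labels during which notifications are
#'   suppressed (changes are still recorded).
#' @param activity_t1,activity_t2 Mean dynamic acceleration thresholds
#'   (m/s^2) separating stationary / light / vigorous activity.
#'
#' @return An object of class `engine_config` (a validated named list).
#' @examples
#' cfg <- engine_config(sensitivity = "high")
#' cfg$eval_period_s
#' @export
engine_config <- function(eval_period_s = 10,
                          baseline_n = 300,
                          min_accuracy = 1,
                          sensitivity = c("normal", "low", "high"),
                          sd_floor_bpm = 1.0,
                          prompt_level = 4,
                          prompt_message = "Take a breath: what are you feeling right now?",
                          gated_activities = "vigorous",
                          activity_t1 = 0.5,
                          activity_t2 = 3.0) {
  sensitivity <- match.arg(sensitivity)
  cfg <- structure(
    list(
      eval_period_s = as.numeric(eval_period_s),
      baseline_n = as.integer(baseline_n),
      min_accuracy = as.integer(min_accuracy),
      sensitivity = sensitivity,
      sd_floor_bpm = as.numeric(sd_floor_bpm),
      prompt_level = as.integer(prompt_level),
      prompt_message = as.character(prompt_message),
      gated_activities = as.character(gated_activities),
      activity_t1 = as.numeric(activity_t1),
      activity_t2 = as.numeric(activity_t2)
    ),
    class = "engine_config"
  )
  validate_engine_config(cfg)
}

validate_engine_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!isTRUE(cfg$eval_period_s > 0)) {
    abort("`eval_period_s` must be a positive number of seconds.")
  }
  if (!isTRUE(cfg$baseline_n >= 2)) {
    abort("`baseline_n` must be at least 2.")
  }
  if (!isTRUE(cfg$min_accuracy >= -1L && cfg$min_accuracy <= 3L)) {
    abort("`min_accuracy` must be an integer in -1..3.")
  }
  if (!cfg$sensitivity %in% names(sensitivity_multipliers())) {
    abort("`sensitivity` must be one of 'low', 'normal', 'high'.")
  }
  if (!isTRUE(cfg$sd_floor_bpm > 0)) {
    abort("`sd_floor_bpm` must be > 0.")
  }
  if (!isTRUE(cfg$prompt_level >= 1L && cfg$prompt_level <= 5L)) {
    abort("`prompt_level` must be in 1..5.")
  }
  if (length(cfg$prompt_message) != 1L || !nzchar(cfg$prompt_message)) {
    abort("`prompt_message` must be a single non-empty string.")
  }
  if (!all(cfg$gated_activities %in% activity_labels())) {
    abort("`gated_activities` must be a subset of stationary/light/vigorous.")
  }
  if (!isTRUE(cfg$activity_t1 >= 0 && cfg$activity_t1 < cfg$activity_t2)) {
    abort("activity thresholds must satisfy 0 <= t1 < t2.")
  }
  cfg
}

#' Read or write an engine configuration file
#'
#' Configurations are stored as flat YAML or JSON with the same field names
#' as [engine_config()]. The format is inferred from the file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param path File path.
#' @return `read_engine_config()` returns an `engine_config`;
#'   `write_engine_config()` returns `path` invisibly.
#' @export
read_engine_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "pcea_data_error")
  }
  vals <- switch(config_format(path),
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE)
  )
  unknown <- setdiff(names(vals), names(formals(engine_config)))
  if (length(unknown)) {
    abort(paste0("Unknown config fields: ", paste(unknown, collapse = ", ")),
          class = "pcea_data_error")
  }
  do.call(engine_config, vals)
}

#' @rdname read_engine_config
#' @param config An `engine_config`.
#' @export
write_engine_config <- function(config, path) {
  config <- validate_engine_config(config)
  vals <- unclass(config)
  switch(config_format(path),
    yaml = yaml::write_yaml(vals, path),
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE, pretty = TRUE)
  )
  invisible(path)
}

config_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) "yaml"
  else if (ext == "json") "json"
  else abort("Config files must end in .yaml, .yml or .json.")
}

#' @export
print.engine_config <- function(x, ...) {
  cat("<engine_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-17s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
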