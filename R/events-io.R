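#' Sensor event logs
#'
#' A sensor event is one wrist-PPG heart-rate reading: an integral timestamp
#' in milliseconds since the Unix epoch, a heart rate in beats/min, a Wear-OS
#' style accuracy code from -1 (no skin contact) to 3 (most accurate), and an
#' opaque `source_id` naming the device or session. Accelerometer events
#' carry a timestamp and tri-axial acceleration in m/s^2. Both logs are kept
#' as tibbles sorted non-decreasing by timestamp; ties keep input order.
#'
#' @name event-logs
#' @keywords internal
NULL

event_cols <- c("timestamp", "hr_bpm", "accuracy", "source_id")
accel_cols <- c("timestamp", "ax", "ay", "az")
timeline_cols <- c("timestamp", "level", "prev_level", "hr_bpm", "activity", "note")
diary_cols <- c("timestamp", "text", "emoticon")

#' Read a heart-rate sensor event log
#'
#' Reads `timestamp,hr_bpm,accuracy,source_id` records from an RFC-4180 CSV
#' (header mandatory, UTF-8) or a JSON-lines file, validates every row, and
#' returns the events sorted by timestamp (stable, so simultaneous events
#' keep their on-disk order). Malformed rows -- accuracy outside -1..3, a
#' negative timestamp, or a missing/non-positive heart rate on a row whose
#' accuracy is 0 or higher -- are reported by row number and abort the read.
#' A reading with accuracy -1 may carry an empty heart-rate field. Heart
#' rates outside the physiological 25-250 bpm range are flagged with a
#' warning but never dropped: dropping is the quality filter's job.
#'
#' @param path Path to the log file.
#' @param format `"csv"` or `"jsonl"`; defaults to the file extension.
#' @return A tibble with columns `timestamp` (double ms), `hr_bpm` (double),
#'   `accuracy` (integer), `source_id` (character), sorted by timestamp.
#' @seealso [quality_filter()], [write_event_log()]
#' @export
read_event_log <- function(path, format = c("auto", "csv", "jsonl")) {
  df <- read_log_file(path, match.arg(format), event_cols,
                      col_types = readr::cols(
                        timestamp = readr::col_double(),
                        hr_bpm = readr::col_double(),
                        accuracy = readr::col_integer(),
                        source_id = readr::col_character()
                      ))
  validate_events(df, path)
}

#' @rdname read_event_log
#' @export
read_accel_log <- function(path, format = c("auto", "csv", "jsonl")) {
  df <- read_log_file(path, match.arg(format), accel_cols,
                      col_types = readr::cols(.default = readr::col_double()))
  validate_accel(df, path)
}

#' Write a sensor event or accelerometer log
#'
#' Inverse of [read_event_log()] / [read_accel_log()]; round-trips
#' losslessly through the matching reader.
#'
#' @param events,accel Tibble as returned by the matching reader.
#' @inheritParams read_event_log
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path, format = c("auto", "csv", "jsonl")) {
  events <- validate_events(events, "events")
  write_log_file(events[event_cols], path, match.arg(format))
}

#' @rdname write_event_log
#' @export
write_accel_log <- function(accel, path, format = c("auto", "csv", "jsonl")) {
  accel <- validate_accel(accel, "accel")
  write_log_file(accel[accel_cols], path, match.arg(format))
}

#' Filter sensor events by accuracy code
#'
#' Keeps only events whose accuracy code is at least `min_accuracy`,
#' preserving order. The deployed engine keeps readings with accuracy 1 and
#' higher; `min_accuracy = -1` keeps everything. Filtering is idempotent and
#' never reorders.
#'
#' @param events Sensor event tibble.
#' @param min_accuracy Integer in -1..3.
#' @return The retained events, same columns and relative order.
#' @export
quality_filter <- function(events, min_accuracy = 1) {
  check_event_frame(events, event_cols, "events")
  if (length(min_accuracy) != 1L || is.na(min_accuracy) ||
      min_accuracy < -1 || min_accuracy > 3) {
    abort("`min_accuracy` must be a single integer in -1..3.")
  }
  events[!is.na(events$accuracy) & events$accuracy >= min_accuracy, , drop = FALSE]
}

#' Read or write a change-record timeline
#'
#' Timelines hold the detected level changes: columns `timestamp`, `level`,
#' `prev_level` (NA for the first record), `hr_bpm`, `activity`, `note`.
#' Empty notes are stored as `""`; CSV quoting follows RFC 4180 so notes may
#' contain commas and newlines. `read_timeline(write_timeline(x))` is
#' field-for-field lossless.
#'
#' @param records Timeline tibble (see [record_change()]); must be
#'   time-ordered.
#' @inheritParams read_event_log
#' @return `write_timeline()` returns `path` invisibly; `read_timeline()`
#'   the records tibble.
#' @export
write_timeline <- function(records, path, format = c("auto", "csv", "jsonl")) {
  records <- validate_timeline(records)
  write_log_file(records[timeline_cols], path, match.arg(format))
}

#' @rdname write_timeline
#' @export
read_timeline <- function(path, format = c("auto", "csv", "jsonl")) {
  df <- read_log_file(path, match.arg(format), timeline_cols,
                      col_types = readr::cols(
                        timestamp = readr::col_double(),
                        level = readr::col_integer(),
                        prev_level = readr::col_integer(),
                        hr_bpm = readr::col_double(),
                        activity = readr::col_character(),
                        note = readr::col_character()
                      ))
  df$note[is.na(df$note)] <- ""
  validate_timeline(df)
}

#' @rdname write_timeline
#' @param diary Diary tibble with columns `timestamp`, `text`, `emoticon`
#'   (see [add_diary()]).
#' @export
write_diary <- function(diary, path, format = c("auto", "csv", "jsonl")) {
  check_event_frame(diary, diary_cols, "diary")
  write_log_file(diary[diary_cols], path, match.arg(format))
}

#' @rdname write_timeline
#' @export
read_diary <- function(path, format = c("auto", "csv", "jsonl")) {
  df <- read_log_file(path, match.arg(format), diary_cols,
                      col_types = readr::cols(
                        timestamp = readr::col_double(),
                        text = readr::col_character(),
                        emoticon = readr::col_character()
                      ))
  df$text[is.na(df$text)] <- ""
  arrange(df, .data$timestamp)
}

# ---- internals --------------------------------------------------------------

log_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "csv"
  else if (ext %in% c("jsonl", "ndjson")) "jsonl"
  else abort(paste0("Cannot infer format from extension of '", path,
                    "'; pass format = 'csv' or 'jsonl'."))
}

read_log_file <- function(path, format, cols, col_types) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "pcea_data_error")
  }
  format <- log_format(path, format)
  if (format == "csv") {
    df <- readr::read_csv(path, col_types = col_types, na = "",
                          progress = FALSE, show_col_types = FALSE)
    probs <- readr::problems(df)
    if (nrow(probs) > 0) {
      abort(paste0("Malformed rows in ", path, ": row(s) ",
                   paste(unique(probs$row), collapse = ", ")),
            class = "pcea_data_error")
    }
  } else {
    df <- read_jsonl(path, cols)
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0(path, " lacks required column(s): ",
                 paste(missing, collapse = ", ")), class = "pcea_data_error")
  }
  as_tibble(df)[cols]
}

write_log_file <- function(df, path, format) {
  format <- log_format(path, format)
  ok <- dir.exists(dirname(path))
  if (!ok) {
    abort(paste0("Cannot write to ", path, ": directory does not exist."),
          class = "pcea_data_error")
  }
  if (format == "csv") {
    readr::write_csv(df, path, na = "", progress = FALSE)
  } else {
    write_jsonl(df, path)
  }
  invisible(path)
}

read_jsonl <- function(path, cols) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::as_tibble(setNames(rep(list(logical(0)), length(cols)), cols)))
  }
  rows <- purrr::imap(lines, function(l, i) {
    obj <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    if (is.null(obj) || !is.list(obj)) {
      abort(paste0("Malformed JSON on line ", i, " of ", path),
            class = "pcea_data_error")
    }
    obj[vapply(obj, is.null, logical(1))] <- NA
    as_tibble(obj[intersect(names(obj), cols)])
  })
  bind_rows(rows)
}

write_jsonl <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(df) > 0) {
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                  na = "null", digits = NA), con)
    }
  }
  invisible(path)
}

check_event_frame <- function(df, cols, what) {
  if (!is.data.frame(df)) {
    abort(paste0("`", what, "` must be a data frame."))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0("`", what, "` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(df)
}

validate_events <- function(df, what) {
  check_event_frame(df, event_cols, "events")
  df <- as_tibble(df)
  df$accuracy <- as.integer(df$accuracy)
  bad_acc <- which(is.na(df$accuracy) | df$accuracy < -1L | df$accuracy > 3L)
  bad_ts <- which(is.na(df$timestamp) | df$timestamp < 0)
  # hr must be a finite positive number whenever the sensor claims contact
  bad_hr <- which(df$accuracy >= 0L &
                    (!is.finite(df$hr_bpm) | df$hr_bpm <= 0))
  bad <- sort(unique(c(bad_acc, bad_ts, bad_hr)))
  if (length(bad)) {
    abort(paste0("Malformed sensor event row(s) in ", what, ": ",
                 paste(bad, collapse = ", "),
                 " (accuracy must be in -1..3, timestamp >= 0, and hr_bpm a ",
                 "positive finite number when accuracy >= 0)."),
          class = "pcea_data_error")
  }
  odd <- sum(df$accuracy >= 0L & (df$hr_bpm < 25 | df$hr_bpm > 250), na.rm = TRUE)
  if (odd > 0) {
    warn(paste0(odd, " reading(s) in ", what,
                " outside 25-250 bpm; kept (only the accuracy filter drops rows)."))
  }
  arrange(df, .data$timestamp)
}

validate_accel <- function(df, what) {
  check_event_frame(df, accel_cols, "accel")
  df <- as_tibble(df)
  bad <- which(is.na(df$timestamp) | df$timestamp < 0 |
                 !is.finite(df$ax) | !is.finite(df$ay) | !is.finite(df$az))
  if (length(bad)) {
    abort(paste0("Malformed accelerometer row(s) in ", what, ": ",
                 paste(bad, collapse = ", ")), class = "pcea_data_error")
  }
  arrange(df, .data$timestamp)
}

validate_timeline <- function(df) {
  check_event_frame(df, timeline_cols, "records")
  df <- as_tibble(df)
  df$level <- as.integer(df$level)
  df$prev_level <- as.integer(df$prev_level)
  df$note <- as.character(df$note)
  df$note[is.na(df$note)] <- ""
  if (is.unsorted(df$timestamp)) {
    abort("Timeline records must be in chronological order.",
          class = "pcea_data_error")
  }
  df
}
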