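#' Empty timeline and diary
#'
#' The timeline is the chronological record of every detected level change;
#' each record carries the change fields plus an editable free-text note
#' (empty on creation). The diary is an independent chronological list of
#' user entries with an optional emoticon tag.
#'
#' @return Zero-row tibbles with the canonical columns.
#' @export
empty_timeline <- function() {
  tibble(timestamp = numeric(0), level = integer(0), prev_level = integer(0),
         hr_bpm = numeric(0), activity = character(0), note = character(0))
}

#' @rdname empty_timeline
#' @export
empty_diary <- function() {
  tibble(timestamp = numeric(0), text = character(0), emoticon = character(0))
}

#' Record level changes on the timeline
#'
#' Appends change events as records with an empty note. Every change is
#' recorded regardless of activity gating -- gating suppresses
#' notifications, never recording. Records must arrive in chronological
#' order.
#'
#' @param records Timeline tibble (see [empty_timeline()]).
#' @param changes One or more change events (rows of a [run_stream()]
#'   result or an [evaluate()] change).
#' @return The grown timeline tibble.
#' @export
record_change <- function(records, changes) {
  records <- validate_timeline(records)
  check_event_frame(changes, c("timestamp", "level", "prev_level", "hr_bpm",
                               "activity"), "changes")
  if (nrow(changes) == 0L) return(records)
  new <- tibble(
    timestamp = as.numeric(changes$timestamp),
    level = as.integer(changes$level),
    prev_level = as.integer(changes$prev_level),
    hr_bpm = as.numeric(changes$hr_bpm),
    activity = as.character(changes$activity),
    note = if ("note" %in% names(changes)) {
      n <- as.character(changes$note); n[is.na(n)] <- ""; n
    } else ""
  )
  out <- bind_rows(records, new)
  if (is.unsorted(out$timestamp)) {
    abort("Changes must be appended in chronological order.",
          class = "pcea_data_error")
  }
  out
}

#' Add or edit the note on a timeline record
#'
#' @param records Timeline tibble.
#' @param record_index 1-based index of the record.
#' @param text Replacement note text.
#' @return The timeline with the note set; all other fields unchanged.
#' @export
add_note <- function(records, record_index, text) {
  records <- validate_timeline(records)
  if (length(record_index) != 1L || is.na(record_index) ||
      record_index < 1 || record_index > nrow(records)) {
    abort(paste0("No timeline record with index ", record_index, "."),
          class = "pcea_data_error")
  }
  records$note[record_index] <- as.character(text)
  records
}

#' Append a diary entry
#'
#' Diary entries are independent of detected changes; they let the user
#' comment on experiences over longer stretches of time. Entries are kept
#' in chronological order whatever order they are added in.
#'
#' @param diary Diary tibble (see [empty_diary()]).
#' @param timestamp Entry time, ms since epoch.
#' @param text Entry text.
#' @param emoticon Optional emoticon tag (`NA` for none).
#' @return The diary tibble, chronologically sorted.
#' @export
add_diary <- function(diary, timestamp, text, emoticon = NA_character_) {
  check_event_frame(diary, diary_cols, "diary")
  entry <- tibble(timestamp = as.numeric(timestamp), text = as.character(text),
                  emoticon = as.character(emoticon))
  arrange(bind_rows(as_tibble(diary), entry), .data$timestamp)
}

#' The most recent level changes
#'
#' The dashboard shows the last `n` (by default 3) detected changes, most
#' recent first; fewer if the timeline is shorter.
#'
#' @param records Timeline tibble.
#' @param n Number of records to return.
#' @return Up to `n` records, most recent first.
#' @export
latest_changes <- function(records, n = 3) {
  records <- validate_timeline(records)
  if (n < 0) abort("`n` must be >= 0.")
  k <- min(n, nrow(records))
  if (k == 0) return(records[0, ])
  records[seq(nrow(records), by = -1L, length.out = k), ]
}

#' Notification policy for detected changes
#'
#' Decides what the user is told about each change. When the classified
#' activity is in `config$gated_activities` nothing is emitted (the change
#' is still recorded on the timeline). Otherwise every change produces a
#' haptic (vibration) notification, and changes reaching
#' `config$prompt_level` or higher on the positive side additionally
#' produce a textual prompt with the user's configured message, intended to
#' trigger reflection on the current arousal. Below-baseline levels never
#' prompt.
#'
#' @param changes Change events (rows of a [run_stream()] result).
#' @param config An [engine_config()].
#' @return A tibble of notifications: `kind` (`"haptic"`/`"prompt"`),
#'   `timestamp`, `level`, `message` (`NA` for haptics).
#' @export
notify_policy <- function(changes, config = engine_config()) {
  config <- validate_engine_config(config)
  check_event_frame(changes, c("timestamp", "level", "activity"), "changes")
  empty <- tibble(kind = character(0), timestamp = numeric(0),
                  level = integer(0), message = character(0))
  if (nrow(changes) == 0L) return(empty)
  ungated <- changes[!changes$activity %in% config$gated_activities, ,
                     drop = FALSE]
  if (nrow(ungated) == 0L) return(empty)
  haptic <- tibble(kind = "haptic", timestamp = as.numeric(ungated$timestamp),
                   level = as.integer(ungated$level), message = NA_character_)
  hi <- ungated[ungated$level >= config$prompt_level, , drop = FALSE]
  prompt <- tibble(kind = "prompt", timestamp = as.numeric(hi$timestamp),
                   level = as.integer(hi$level),
                   message = config$prompt_message)
  out <- bind_rows(haptic, prompt)
  out[order(out$timestamp, match(out$kind, c("haptic", "prompt"))), ]
}

#' Dashboard summary of a timeline
#'
#' The batch analogue of the app's dashboard: overall status (record and
#' diary counts, current level), the last `n_latest` detected changes, and a
#' level-occupancy histogram whose counts sum to the record count.
#'
#' @param records Timeline tibble.
#' @param diary Optional diary tibble.
#' @param n_latest How many recent changes to show.
#' @return A `pcea_dashboard` list: `status`, `last_changes`, `occupancy`.
#' @export
dashboard_summary <- function(records, diary = NULL, n_latest = 3) {
  records <- validate_timeline(records)
  lv <- factor(records$level, levels = c(-5:-1, 1:5))
  occupancy <- tibble(level = as.integer(as.character(levels(lv))),
                      n = as.integer(table(lv)))
  structure(
    list(
      status = list(
        n_records = nrow(records),
        n_diary = if (is.null(diary)) 0L else nrow(diary),
        current_level = if (nrow(records)) records$level[nrow(records)]
                        else NA_integer_,
        last_change_at = if (nrow(records)) records$timestamp[nrow(records)]
                         else NA_real_
      ),
      last_changes = latest_changes(records, n_latest),
      occupancy = occupancy
    ),
    class = "pcea_dashboard"
  )
}

#' @export
print.pcea_dashboard <- function(x, ...) {
  s <- x$status
  cat("== Arousal engine dashboard ==\n")
  cat(sprintf("Records: %d | diary entries: %d | current level: %s\n",
              s$n_records, s$n_diary,
              if (is.na(s$current_level)) "none" else s$current_level))
  cat(sprintf("Last %d change(s):\n", nrow(x$last_changes)))
  if (nrow(x$last_changes)) {
    for (i in seq_len(nrow(x$last_changes))) {
      r <- x$last_changes[i, ]
      cat(sprintf("  %s  level %+d (%.1f bpm, %s)%s\n",
                  format_ms(r$timestamp), r$level, r$hr_bpm, r$activity,
                  if (nzchar(r$note)) paste0("  note: ", r$note) else ""))
    }
  } else cat("  (none)\n")
  cat("Level occupancy:\n")
  occ <- x$occupancy[x$occupancy$n > 0, ]
  if (nrow(occ)) {
    for (i in seq_len(nrow(occ))) {
      cat(sprintf("  %+d: %d\n", occ$level[i], occ$n[i]))
    }
  } else cat("  (empty)\n")
  invisible(x)
}

format_ms <- function(ms) {
  format(as.POSIXct(ms / 1000, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%d %H:%M:%S")
}
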