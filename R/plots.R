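#' Plot a heart-rate stream against its baseline bands
#'
#' Line plot of heart rate over time with the personal mean and the level
#' band edges (mean plus/minus multiples of the sensitivity-scaled SD)
#' overlaid; readings failing the accuracy filter are marked.
#'
#' @param events Sensor event tibble.
#' @param baseline Optional [`pcea_baseline`][finalize_baseline] to draw
#'   band edges for.
#' @param sensitivity Sensitivity used for the band spacing.
#' @param min_accuracy Accuracy threshold used to mark rejected readings.
#' @return A ggplot object.
#' @export
plot_stream <- function(events, baseline = NULL, sensitivity = "normal",
                        min_accuracy = 1) {
  check_event_frame(events, event_cols, "events")
  df <- mutate(as_tibble(events),
               t_min = (.data$timestamp - min(.data$timestamp)) / 60000,
               kept = .data$accuracy >= min_accuracy)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_min, y = .data$hr_bpm)) +
    ggplot2::geom_line(colour = "grey40", na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$kept), size = 0.6,
                        na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "red"),
                                 name = "passes filter") +
    ggplot2::labs(x = "time (min)", y = "heart rate (bpm)")
  if (!is.null(baseline)) {
    k <- sensitivity_multiplier(sensitivity) * baseline$sd_hr
    edges <- baseline$mean_hr + k * c(-4:-1, 0, 1:4)
    p <- p +
      ggplot2::geom_hline(yintercept = baseline$mean_hr, colour = "steelblue") +
      ggplot2::geom_hline(yintercept = setdiff(edges, baseline$mean_hr),
                          colour = "steelblue", linetype = "dashed",
                          alpha = 0.5)
  }
  p
}

#' Step plot of an engine run
#'
#' Shows the effective arousal level over the evaluation windows, with the
#' emitted change events marked.
#'
#' @param object A [`pcea_run`][run_stream] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcea_run
#' @export
autoplot.pcea_run <- function(object, ...) {
  win <- attr(object, "windows")
  changes <- tidy(object)
  if (is.null(win) || nrow(win) == 0) {
    abort("This run has no evaluation windows to plot.")
  }
  t0 <- min(win$timestamp)
  win <- mutate(win, t_min = (.data$timestamp - t0) / 60000)
  changes <- mutate(changes, t_min = (.data$timestamp - t0) / 60000)
  ggplot2::ggplot(win, ggplot2::aes(x = .data$t_min,
                                    y = .data$level_effective)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::geom_point(data = changes,
                        ggplot2::aes(y = .data$level, colour = .data$activity),
                        size = 2) +
    ggplot2::scale_y_continuous(breaks = c(-5:-1, 1:5), limits = c(-5, 5)) +
    ggplot2::labs(x = "time (min)", y = "arousal level", colour = "activity")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Level-occupancy histogram of a timeline
#'
#' Bar chart of how many recorded changes landed on each of the ten levels;
#' counts sum to the record count.
#'
#' @param records Timeline tibble.
#' @return A ggplot object.
#' @export
plot_level_occupancy <- function(records) {
  occ <- dashboard_summary(records)$occupancy
  occ$level <- factor(occ$level, levels = c(-5:-1, 1:5))
  ggplot2::ggplot(occ, ggplot2::aes(x = .data$level, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "arousal level", y = "recorded changes")
}
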