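#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a personal baseline
#'
#' @param x A [`pcea_baseline`][finalize_baseline].
#' @param ... Unused.
#' @return `tidy()`: one row per estimated quantity (`mean_hr`, `sd_hr`)
#'   with its estimate in bpm. `glance()`: a one-row summary with the
#'   sample count, override flag and SD floor.
#' @method tidy pcea_baseline
#' @export
tidy.pcea_baseline <- function(x, ...) {
  tibble(term = c("mean_hr", "sd_hr"),
         estimate = c(x$mean_hr, x$sd_hr),
         unit = "bpm")
}

#' @rdname tidy.pcea_baseline
#' @method glance pcea_baseline
#' @export
glance.pcea_baseline <- function(x, ...) {
  tibble(n = x$n, overridden = x$overridden, sd_floor = x$sd_floor)
}

#' Tidy an engine run
#'
#' @param x A [`pcea_run`][run_stream] result.
#' @param ... Unused.
#' @return `tidy()`: the change events as a plain tibble. `glance()`: a
#'   one-row summary with change and window counts, the time span and the
#'   level range visited.
#' @method tidy pcea_run
#' @export
tidy.pcea_run <- function(x, ...) {
  as_tibble(unclass_run(x))
}

#' @rdname tidy.pcea_run
#' @method glance pcea_run
#' @export
glance.pcea_run <- function(x, ...) {
  win <- attr(x, "windows")
  tibble(
    n_changes = nrow(x),
    n_windows = if (is.null(win)) NA_integer_ else nrow(win),
    t_start = if (nrow(x)) min(x$timestamp) else NA_real_,
    t_end = if (nrow(x)) max(x$timestamp) else NA_real_,
    min_level = if (nrow(x)) min(x$level) else NA_integer_,
    max_level = if (nrow(x)) max(x$level) else NA_integer_
  )
}

unclass_run <- function(x) {
  attr(x, "windows") <- NULL
  attr(x, "config") <- NULL
  attr(x, "baseline") <- NULL
  class(x) <- setdiff(class(x), "pcea_run")
  x
}
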