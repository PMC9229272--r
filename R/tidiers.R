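#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a rotation result into one row per cycle
#'
#' @param x A `rotation_result`.
#' @param ... Ignored.
#' @return A tibble with one row per area cycle: `cycle`, `trough_start`,
#'   `trough_end`, `spacing_frames`, `rpm`.
#' @export
tidy.rotation_result <- function(x, ...) {
  k <- x$n_cycles
  tibble::tibble(
    cycle = seq_len(k),
    trough_start = x$trough_frames[seq_len(k)],
    trough_end = x$trough_frames[seq_len(k) + 1L],
    spacing_frames = diff(x$trough_frames),
    rpm = x$per_cycle_rpm
  )
}

#' One-row summary of a rotation result
#'
#' @param x A `rotation_result`.
#' @param ... Ignored.
#' @return A one-row tibble: `mean_rpm`, `mean_rpm_pooled`,
#'   `max_deviation_rpm`, `n_cycles`, `symmetry_factor`, `fps`,
#'   `smoothing_width`.
#' @export
glance.rotation_result <- function(x, ...) {
  tibble::tibble(
    mean_rpm = x$mean_rpm,
    mean_rpm_pooled = x$mean_rpm_pooled,
    max_deviation_rpm = x$max_deviation_rpm,
    n_cycles = x$n_cycles,
    symmetry_factor = x$symmetry_factor,
    fps = x$fps,
    smoothing_width = x$smoothing_width
  )
}
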