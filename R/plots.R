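#' Plot segment trajectories in the pelvic frame
#'
#' Draws the path of each urethral segment's origin relative to the
#' IPP-anchored coordinate system, one panel per subject-maneuver, with
#' the rest position marked. Axes are in mm: posterior to the right,
#' superior up.
#'
#' @param trajectories Long tibble as produced by [run_subject()] /
#'   [write_trajectories()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories) {
  ggplot2::ggplot(trajectories,
                  ggplot2::aes(.data$x_mm, .data$y_mm, colour = .data$roi)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::geom_point(data = dplyr::filter(trajectories, .data$frame == 0),
                        shape = 21, fill = "black", size = 1.5) +
    ggplot2::facet_grid(subject ~ maneuver) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm, posterior +)", y = "y (mm, superior +)",
                  colour = "segment") +
    ggplot2::theme_minimal()
}

#' Plot group-level displacement summaries
#'
#' Mean +/- SEM of a metric per segment, maneuver and group.
#'
#' @param summary A [cohort_summary()] tibble.
#' @param metric Metric to display (default `"dmag_mm"`).
#' @return A ggplot object.
#' @export
plot_group_summary <- function(summary, metric = "dmag_mm") {
  d <- summary[summary$metric == metric, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$roi, .data$mean,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::facet_wrap(~maneuver) +
    ggplot2::labs(x = NULL, y = metric, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot.cohort_result` shows the group summary of displacement
#' magnitude; `autoplot.kinematic_record` shows the per-frame displacement
#' components and magnitude of one segment.
#'
#' @param object A `cohort_result` or `kinematic_record`.
#' @param ... Passed on to the underlying plot function.
#' @return A ggplot object.
#' @export
autoplot.cohort_result <- function(object, ...) {
  plot_group_summary(object$summary, ...)
}

#' @rdname autoplot.cohort_result
#' @export
autoplot.kinematic_record <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[c("frame", "dx_mm", "dy_mm", "dmag_mm")],
    c("dx_mm", "dy_mm", "dmag_mm"),
    names_to = "component", values_to = "mm")
  ggplot2::ggplot(long, ggplot2::aes(.data$frame, .data$mm,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "displacement (mm)") +
    ggplot2::theme_minimal()
}
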