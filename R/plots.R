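#' Plot delta-FRET time courses
#'
#' Group mean +/- SEM per treatment over the recording day, with per-animal
#' traces behind.
#'
#' @param delta_fret Long tibble with `animal_id`, `treatment`, `hour`,
#'   `delta_fret` columns (e.g. `tidy()` of a processed experiment).
#' @return A ggplot object.
#' @export
plot_delta_fret <- function(delta_fret) {
  stopifnot(is.data.frame(delta_fret))
  means <- delta_fret |>
    dplyr::group_by(.data$treatment, .data$hour) |>
    dplyr::summarise(
      mean = mean(.data$delta_fret),
      sem = stats::sd(.data$delta_fret) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(means, ggplot2::aes(x = .data$hour, y = .data$mean,
                                      colour = .data$treatment)) +
    ggplot2::geom_line(
      data = delta_fret,
      ggplot2::aes(y = .data$delta_fret,
                   group = interaction(.data$animal_id, .data$treatment)),
      alpha = 0.25, linewidth = 0.3
    ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem, fill = .data$treatment),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Hours post-administration",
                  y = expression(Delta * "FRET (%)"),
                  colour = "Treatment", fill = "Treatment") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_delta_fret autoplot method for processed experiments.
#' @param object A `photofret_experiment`.
#' @param ... Unused.
#' @method autoplot photofret_experiment
#' @export
autoplot.photofret_experiment <- function(object, ...) {
  plot_delta_fret(object$delta_fret)
}

#' Plot a frame stream
#'
#' Raw ROI intensity against session time, coloured by LED state; a quick QC
#' view of the lead-in, the interleave and any artifacts.
#'
#' @param object Tibble of frames (canonical columns).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_frames <- function(object, ...) {
  stopifnot(is.data.frame(object))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$timestamp,
                                       y = .data$roi_intensity,
                                       colour = factor(.data$led_state))) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::labs(x = "Session time (s)", y = "ROI intensity (counts)",
                  colour = "LED") +
    ggplot2::theme_minimal()
}
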