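#' Diagnostic plot of a walking-bout detection
#'
#' Plots the detrended 3D magnitude with detected bouts shaded by kind:
#' surviving walking bouts plus the transition- and duration-rejected ones
#' kept for audit.
#'
#' @param object A `walk_detection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.walk_detection <- function(object, ...) {
  bouts <- tidy(object)
  mag <- as_tibble(object$magnitude)
  p <- ggplot2::ggplot(mag, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "grey30")
  if (nrow(bouts) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = bouts,
      ggplot2::aes(xmin = .data$start_s,
                   xmax = .data$start_s + .data$duration_s,
                   ymin = -Inf, ymax = Inf, fill = .data$kind),
      alpha = 0.25, inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_hline(yintercept = object$config$activity_threshold_g,
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "detrended 3D magnitude (g)",
                  fill = "bout kind",
                  title = sprintf("walking-bout detection (%s mode)",
                                  object$config$mode)) +
    ggplot2::theme_minimal()
}

#' Plot a labelled synthetic trace
#'
#' Shows the three acceleration axes with the ground-truth walking segments
#' shaded.
#'
#' @param object A `labeled_trace` from [build_scenario()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.labeled_trace <- function(object, ...) {
  fs <- trace_fs(object$trace)
  long <- as_tibble(object$trace) |>
    tidyr::pivot_longer(c("ax", "ay", "az"), names_to = "axis")
  walks <- object$segments |>
    dplyr::filter(.data$kind == "walk") |>
    dplyr::mutate(start_s = .data$start_frame / fs,
                  end_s = .data$end_frame / fs)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                          colour = .data$axis))
  if (nrow(walks) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = walks,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      fill = "palegreen", alpha = 0.4, inherit.aes = FALSE
    )
  }
  p + ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "acceleration (g)",
                  title = "synthetic labelled trace (truth walking shaded)") +
    ggplot2::theme_minimal()
}

#' Plot cohort evaluation metrics
#'
#' Mean and standard deviation of each metric per detector variant,
#' mirroring the usual mean (s.d.) summary table as a dot-and-error plot.
#'
#' @param reports Per-participant metric rows from [evaluate_cohort()]
#'   (must carry a `mode` column).
#' @return A ggplot object.
#' @export
plot_cohort_metrics <- function(reports) {
  summ <- reports |>
    dplyr::group_by(.data$mode) |>
    dplyr::group_modify(~cohort_average(.x)) |>
    dplyr::ungroup()
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$metric, y = .data$mean,
                                     colour = .data$mode)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = pmax(0, .data$mean - .data$sd),
                   ymax = pmin(1, .data$mean + .data$sd)),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "metric (mean ± s.d.)",
                  colour = "variant") +
    ggplot2::theme_minimal()
}
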