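#' Plot a band-power track
#'
#' Windowed LF power, HF power and their ratio against window center time.
#'
#' @param object A [band_power_track()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot band_power_track
#' @export
autoplot.band_power_track <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(c("lf_ms2", "hf_ms2", "ratio"),
      names_to = "quantity", values_to = "value"
    ) |>
    dplyr::mutate(quantity = factor(.data$quantity,
      levels = c("lf_ms2", "hf_ms2", "ratio"),
      labels = c("LF power (ms²)", "HF power (ms²)", "LF/HF ratio")
    ))
  ggplot2::ggplot(long, ggplot2::aes(.data$window_center_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "window center (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot condition-by-segment mean LF/HF ratios
#'
#' The study's headline figure: grand mean LF/HF per segment and
#' condition, with SD error bars.
#'
#' @param report A [run_study()] report (or its `ratio_summary` tibble).
#' @return A ggplot.
#' @export
plot_segment_ratios <- function(report) {
  summary <- if (inherits(report, "study_report")) report$ratio_summary else report
  summary <- dplyr::mutate(summary,
    segment = factor(.data$segment, levels = unique(.data$segment))
  )
  ggplot2::ggplot(summary, ggplot2::aes(
    .data$segment, .data$mean_ratio,
    fill = .data$condition
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_ratio - .data$sd_ratio,
        ymax = .data$mean_ratio + .data$sd_ratio
      ),
      position = ggplot2::position_dodge(0.8), width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "mean LF/HF ratio", fill = "condition") +
    ggplot2::theme_minimal()
}

#' @rdname plot_segment_ratios
#' @param object A `study_report`.
#' @param ... Unused.
#' @method autoplot study_report
#' @export
autoplot.study_report <- function(object, ...) plot_segment_ratios(object)
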