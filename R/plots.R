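# ggplot2 visualizations.

#' Plot a normalized-cycle power profile
#'
#' Mean band power across the 80-bin normalized SO cycle, with the
#' Down-state half (0-50) shaded and the peak marked.
#'
#' @param object A `cycle_power_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cycle_power_profile
#' @export
autoplot.cycle_power_profile <- function(object, ...) {
  df <- tidy.cycle_power_profile(object)
  smry <- summarize_cycle_power(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase_pct, y = .data$value)) +
    ggplot2::annotate("rect", xmin = 0, xmax = 50, ymin = -Inf,
                      ymax = Inf, alpha = 0.08, fill = "blue") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::filter(
      df, .data$phase_pct == smry$latency_pct
    ), color = "red", size = 2) +
    ggplot2::geom_vline(xintercept = 50, linetype = "dashed") +
    ggplot2::labs(
      x = "normalized SO cycle (0 = Down onset, 50 = Up onset)",
      y = "mean area power (z-scored units)",
      title = if (is.null(object$band)) NULL else
        sprintf("%s band power over the normalized SO cycle",
                as_band_spec(object$band)$name)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a coherence spectrum
#'
#' @param object A `coherence_result`.
#' @param ... Unused.
#' @return A ggplot with the SO search band shaded and the maximum
#'   marked.
#' @method autoplot coherence_result
#' @export
autoplot.coherence_result <- function(object, ...) {
  ggplot2::ggplot(object$spectrum,
                  ggplot2::aes(x = .data$freq_hz, y = .data$coherence)) +
    ggplot2::annotate("rect", xmin = 0.1, xmax = 0.9, ymin = -Inf,
                      ymax = Inf, alpha = 0.08, fill = "blue") +
    ggplot2::geom_line() +
    ggplot2::annotate("point", x = object$max_freq_hz,
                      y = object$max_coherence, color = "red") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "frequency (Hz)",
                  y = "magnitude-squared coherence") +
    ggplot2::theme_minimal()
}

#' Plot a segmented LFP trace
#'
#' @param object A `uds_segmentation`.
#' @param signal Optional voltage series to draw under the state ribbon.
#' @param ... Unused.
#' @return A ggplot with Up-states in red and Down-states in blue.
#' @method autoplot uds_segmentation
#' @export
autoplot.uds_segmentation <- function(object, signal = NULL, ...) {
  st <- object$states
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = st,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf, fill = .data$label),
      alpha = 0.25
    ) +
    ggplot2::scale_fill_manual(values = c(Up = "red", Down = "blue")) +
    ggplot2::labs(x = "time (s)", y = "LFP (mV)", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(signal)) {
    df <- tibble(time_s = (seq_along(signal) - 1) / object$fs_hz,
                 v = signal)
    p <- p + ggplot2::geom_line(
      data = df, ggplot2::aes(x = .data$time_s, y = .data$v),
      linewidth = 0.3
    )
  }
  p
}
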