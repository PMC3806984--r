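#' Plot a UDTF spectrum
#'
#' Log-log magnitude plot of the umbo displacement transfer function.
#'
#' @param object A `udtf_spectrum`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.udtf_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency_hz,
                                       y = .data$magnitude_mm_per_pa)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "UDTF magnitude (mm/Pa)") +
    ggplot2::theme_minimal()
}

#' Plot a measured population summary
#'
#' Geometric-mean curve with the percentile band shaded.
#'
#' @param object A `population_summary`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.population_summary <- function(object, ...) {
  lb <- attr(object, "log_base") %||% 10
  df <- mutate(as_tibble(object), geo_mean = lb^.data$log_mean)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency_hz)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_lower,
                                      ymax = .data$band_upper),
                         fill = "grey75", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$geo_mean), linewidth = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "UDTF magnitude (mm/Pa)") +
    ggplot2::theme_minimal()
}

#' Plot a model-vs-measurement comparison
#'
#' Measured geometric mean and percentile band with the model UDTF
#' overlaid; the divergence band, when present, is marked with a dashed
#' vertical line.
#'
#' @param object An `ear_comparison`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.ear_comparison <- function(object, ...) {
  lb <- 10
  df <- mutate(as_tibble(object), measured = lb^.data$measured_logmean)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency_hz)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_lower,
                                      ymax = .data$band_upper),
                         fill = "grey75", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$measured,
                                    colour = "measured"), linewidth = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$model_mm_per_pa,
                                    colour = "model"), linewidth = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "UDTF magnitude (mm/Pa)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  div <- attr(object, "divergence_hz")
  if (!is.na(div)) {
    p <- p + ggplot2::geom_vline(xintercept = div, linetype = "dashed")
  }
  p
}
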