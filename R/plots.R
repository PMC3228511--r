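#' Plot a moving-average trend with standard-error ribbon
#'
#' The standard multi-day baseline display: a 1-h moving average of a
#' monitored parameter over the recording, with SEM bars as a ribbon.
#'
#' @param trend Long-format trend table from [moving_average()].
#' @param parameter One of the metric column names (default: all present,
#'   faceted).
#' @return A ggplot object.
#' @export
plot_trend <- function(trend, parameter = NULL) {
  if (!is.null(parameter)) trend <- trend[trend$parameter %in% parameter, ]
  if (!nrow(trend)) stop("no trend points to plot")
  ggplot2::ggplot(trend, ggplot2::aes(x = .data$center_s / 3600, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "1-h moving average ± SEM") +
    ggplot2::theme_bw()
}

#' Plot a short waveform snippet
#'
#' Displays the raw pressure waveform over a short interval (3 s by
#' default), the usual per-animal morphology check.
#'
#' @param recording A [pressure_recording()].
#' @param start_s Snippet start time (s).
#' @param duration_s Snippet length (default 3 s).
#' @return A ggplot object.
#' @export
plot_waveform <- function(recording, start_s = 0, duration_s = 3) {
  rate <- recording$sampling_rate_hz
  i0 <- as.integer(round(start_s * rate)) + 1L
  i1 <- min(length(recording$samples), i0 + as.integer(round(duration_s * rate)) - 1L)
  if (i1 <= i0) stop("snippet window is empty")
  df <- data.frame(t = (seq(i0, i1) - 1) / rate,
                   p = recording$samples[i0:i1])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$p)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = sprintf("LVP (%s)", recording$units)) +
    ggplot2::theme_bw()
}
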