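# Plotting methods for signal sets, spectra and screening traces.

#' @export
autoplot.pg_signals <- function(object, channels = c("rppg", "bpm", "y"),
                                ...) {
  fps <- attr(object, "fps")
  long <- tidyr::pivot_longer(as_tibble(object), cols = dplyr::all_of(channels),
                              names_to = "channel", values_to = "value")
  long$time <- long$frame / fps
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     color = .data$region)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL, color = "Region") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pg_spectrum <- function(object, ...) {
  d <- filter(as_tibble(object), .data$bpm <= 300)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bpm, y = .data$power)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::geom_vline(xintercept = c(42, 240), linetype = "dashed",
                        color = "grey60") +
    ggplot2::labs(x = "Frequency (bpm)", y = "Power") +
    ggplot2::theme_minimal()
}

#' Plot motion and light screening traces
#'
#' @param traces A list with `motion` and `light` as returned by
#'   [screening_traces()].
#' @param thresholds Optional [calibrate_thresholds()] output drawn as
#'   horizontal reference lines.
#' @return A ggplot object.
#' @export
plot_screening_traces <- function(traces, thresholds = NULL) {
  d <- bind_rows(
    tibble(frame = traces$motion$frame, value = traces$motion$displacement,
           criterion = "motion (px/frame)"),
    tibble(frame = traces$light$frame, value = traces$light$dy,
           criterion = "light |dY|")
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$frame, y = .data$value)) +
    ggplot2::geom_line(color = "#2166ac", linewidth = 0.4) +
    ggplot2::facet_wrap(~criterion, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Frame", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    ref <- tibble(
      criterion = c("motion (px/frame)", "light |dY|"),
      value = c(thresholds$motion_threshold, thresholds$light_threshold)
    )
    p <- p + ggplot2::geom_hline(data = ref,
                                 ggplot2::aes(yintercept = .data$value),
                                 linetype = "dashed", color = "#b2182b")
  }
  p
}
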