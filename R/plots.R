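#' Plot a photometry trace
#'
#' @param data Data frame with `time_s` and one of `intensity_au` /
#'   `concentration`.
#' @param y Column to plot; defaults to `concentration` if present, else
#'   `intensity_au`.
#' @return A ggplot.
#' @export
plot_trace <- function(data, y = NULL) {
  if (is.null(y)) {
    y <- if ("concentration" %in% names(data)) "concentration" else "intensity_au"
  }
  ggplot2::ggplot(data, ggplot2::aes(.data$time_s / 3600, .data[[y]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (h)", y = y) +
    ggplot2::theme_minimal()
}

#' Plot a hypnogram
#'
#' @param hypnogram Data frame with `bin_start_s` and `state`.
#' @return A ggplot tile strip of vigilance states over time.
#' @export
plot_hypnogram <- function(hypnogram) {
  d <- dplyr::mutate(
    hypnogram,
    state = factor(tolower(.data$state), levels = c("rem", "nrem", "wake")))
  ggplot2::ggplot(d, ggplot2::aes(.data$bin_start_s / 3600, y = 1,
                                  fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "time (h)", y = NULL, fill = "state") +
    ggplot2::theme_minimal()
}
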