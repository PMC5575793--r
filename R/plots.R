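#' Plot an ensemble mean trace with SEM ribbon
#'
#' @param ens Output of [ensemble_mean()].
#' @param protocol Optional [stim_protocol()]; stimuli are shaded.
#' @return A ggplot object.
#' @export
plot_ensemble <- function(ens, protocol = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  gg <- ggplot2::ggplot(ens, ggplot2::aes(x = .data$time_s,
                                          y = .data$mean_dRR))
  if (!is.null(protocol)) {
    stim <- data.frame(xmin = protocol$onsets,
                       xmax = protocol$onsets + protocol$durations)
    gg <- gg + ggplot2::geom_rect(
      data = stim, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      fill = "grey85")
  }
  gg +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_dRR - .data$sem_dRR,
                                      ymax = .data$mean_dRR + .data$sem_dRR),
                         fill = "seagreen", alpha = 0.3) +
    ggplot2::geom_line(color = "seagreen4") +
    ggplot2::labs(x = "time (s)", y = expression(Delta * R / R[0])) +
    ggplot2::theme_minimal()
}

#' Bubble chart of a pressure x duration grid summary
#'
#' Circle area encodes the mean peak response; fill encodes the
#' response fraction — the compact view of how stimulus intensity and
#' duration shape responsiveness.
#'
#' @param grid Output of [summarize_grid()].
#' @return A ggplot object.
#' @export
plot_grid_summary <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(grid, ggplot2::aes(x = factor(.data$pressure),
                                     y = factor(.data$duration))) +
    ggplot2::geom_point(ggplot2::aes(size = .data$mean_peak,
                                     fill = .data$response_fraction),
                        shape = 21, color = "grey30") +
    ggplot2::scale_size_area(max_size = 12,
                             limits = c(0, max(grid$mean_peak, 3))) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "pressure (psi)", y = "duration (s)",
                  size = "mean peak", fill = "response fraction") +
    ggplot2::theme_minimal()
}
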