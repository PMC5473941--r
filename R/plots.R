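# ggplot2 visualizations for the main result types.

#' Plot a dwell-time survival curve with its two-phase fit
#'
#' @param object A `dwell_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dwell_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed),
      fill = "grey70", width = 0.1
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(
      x = "Time after binding (s)", y = "Particles remaining attached (%)",
      title = sprintf(
        "Two-phase fit: w = %.2f, τ fast = %.2g s, τ slow = %.2g s",
        object$w_fast, object$tau_fast_s, object$tau_slow_s
      )
    ) +
    ggplot2::theme_classic()
}

#' Plot a chromatogram with an optional integration window
#'
#' @param object A `chromatogram` or trace tibble.
#' @param window Optional `c(v_start, v_end)` in mL, shaded.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.chromatogram <- function(object, window = NULL, ...) {
  trace <- as_trace(object)
  p <- ggplot2::ggplot(trace, ggplot2::aes(.data$volume_mL, .data$a280)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Elution volume (mL)", y = "A280") +
    ggplot2::theme_classic()
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect",
      xmin = window[1], xmax = window[2],
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue"
    )
  }
  p
}

#' Plot an inter-motor distance histogram
#'
#' @param histogram Output of [distance_histogram()].
#' @return A ggplot.
#' @export
plot_distance_histogram <- function(histogram) {
  ggplot2::ggplot(histogram, ggplot2::aes(
    x = .data$bin_start_nm + (.data$bin_end_nm - .data$bin_start_nm) / 2,
    y = .data$particles
  )) +
    ggplot2::geom_col(width = histogram$bin_end_nm[1] - histogram$bin_start_nm[1]) +
    ggplot2::labs(x = "Inter-motor distance (nm)", y = "Particles") +
    ggplot2::theme_classic()
}

#' Plot a live-cell focus recovery time course
#'
#' Mean background-subtracted focus intensity with a +/- SD ribbon.
#'
#' @param object A `foci_timecourse` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.foci_timecourse <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(.data$time_s, .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Focus intensity (background-subtracted)") +
    ggplot2::theme_classic()
}
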