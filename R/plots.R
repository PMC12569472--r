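#' @importFrom ggplot2 ggplot aes geom_line geom_histogram geom_point
#'   geom_ribbon geom_path geom_vline facet_wrap labs theme_minimal
#'   after_stat geom_errorbar
NULL

#' Plot activation envelopes
#'
#' One facet per channel; optional onset-peak markers.
#'
#' @param object envelope tibble from [emg_envelope()].
#' @param peaks optional `onset_peaks` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.emg_envelope <- function(object, peaks = NULL, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time_s",
                              names_to = "channel", values_to = "activation")
  p <- ggplot(long, aes(x = .data$time_s, y = .data$activation)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~channel, scales = "free_y") +
    labs(x = "time (s)", y = "activation (mV)") +
    theme_minimal()
  if (!is.null(peaks)) {
    p <- p + geom_point(data = peaks,
                        aes(x = .data$time_s, y = .data$height),
                        colour = "red", size = 0.8)
  }
  p
}

#' Plot a delay distribution
#'
#' Histogram of the signed delays with the empirical density overlay and a
#' zero line; the negative fraction is the area left of zero.
#'
#' @param object a `delay_summary`.
#' @param binwidth_ms histogram bin width, ms.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.delay_summary <- function(object, binwidth_ms = 10, ...) {
  d <- tibble::tibble(delta_t_ms = object$delta_t_ms)
  ggplot(d, aes(x = .data$delta_t_ms)) +
    geom_histogram(aes(y = after_stat(density)), binwidth = binwidth_ms,
                   fill = "grey70", colour = "grey30") +
    ggplot2::geom_density(colour = "steelblue") +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = expression(Delta * t ~ "(ms)"), y = "density",
         subtitle = sprintf("%.1f%% negative (n = %d)",
                            object$percent_negative, object$n)) +
    theme_minimal()
}

#' Plot the channel-count ablation
#'
#' Mean test RMSE with an SD ribbon against channel count.
#'
#' @param object an `ablation_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ablation_result <- function(object, ...) {
  ggplot(object$summary, aes(x = .data$count, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                fill = "grey80") +
    geom_line() + geom_point() +
    labs(x = "EMG channels", y = "mean joint RMSE (deg)") +
    theme_minimal()
}

#' Plot a reconstructed midline
#'
#' Anchor points and the smoothed midline of selected samples of a body pose.
#'
#' @param pose `body_pose` tibble.
#' @param samples row indices to draw.
#' @return a ggplot.
#' @export
plot_midline <- function(pose, samples = 1) {
  anchors <- purrr::map_dfr(samples, function(s) {
    tibble::tibble(sample = s,
                   x = as.numeric(pose[s, paste0("x", 1:6)]),
                   y = as.numeric(pose[s, paste0("y", 1:6)]))
  })
  smooth <- purrr::map_dfr(samples, function(s) {
    sm <- smooth_midline(pose, s)
    sm$sample <- s
    sm
  })
  ggplot(smooth, aes(x = .data$x, y = .data$y, group = .data$sample)) +
    geom_path(colour = "steelblue") +
    geom_point(data = anchors, size = 1.5) +
    ggplot2::coord_equal() +
    labs(x = "x (cm)", y = "y (cm)") +
    theme_minimal()
}

#' Plot per-condition negative-delay fractions
#'
#' @param comparison tibble from [compare_conditions()].
#' @return a ggplot.
#' @export
plot_condition_comparison <- function(comparison) {
  ggplot(dplyr::filter(comparison, .data$channel != "pooled"),
         aes(x = .data$channel, y = .data$percent_negative,
             fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    labs(x = "channel", y = "% negative delays") +
    theme_minimal()
}
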