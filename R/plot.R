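#' Violin/jitter plot of per-particle intensity distributions
#'
#' @param particles A tibble with an intensity column and a grouping column
#'   (e.g. the `particles` table of [run_amplification_experiment()]).
#' @param group,value Column names (strings) for grouping and intensity.
#' @param log_scale Log10 y axis (intensities are right-skewed).
#' @return A ggplot.
#' @export
plot_intensity_distributions <- function(particles, group = "method",
                                         value = "integrated",
                                         log_scale = TRUE) {
  p <- ggplot2::ggplot(
    particles,
    ggplot2::aes(x = .data[[group]], y = .data[[value]], fill = .data[[group]])
  ) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_jitter(width = 0.12, size = 0.3, alpha = 0.3, show.legend = FALSE) +
    ggplot2::labs(
      x = NULL, y = "integrated intensity (ADU)",
      title = "Single-particle intensity distributions"
    ) +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
autoplot.ev_stability <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(x = .data$timepoint, y = .data$retention)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::expand_limits(y = 0) +
    ggplot2::labs(
      x = "continuous excitation (min)", y = "signal retention",
      title = "Photobleaching stability profile"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ev_coloc <- function(object, ...) {
  if (is.null(object$pairs) || nrow(object$pairs) == 0) {
    stop("no double-positive pairs to plot", call. = FALSE)
  }
  ggplot2::ggplot(
    object$pairs,
    ggplot2::aes(x = .data$int_a, y = .data$int_b)
  ) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "channel A integrated intensity (ADU)",
      y = "channel B integrated intensity (ADU)",
      title = sprintf(
        "Double-positive intensity correlation (r = %.2f)",
        object$r
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ev_normcounts <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$condition, y = .data$normalized_pct)
  ) +
    ggplot2::stat_summary(fun = mean, geom = "col", alpha = 0.7) +
    ggplot2::geom_jitter(width = 0.1, size = 1) +
    ggplot2::labs(
      x = NULL, y = "normalized EV counts (%)",
      title = "Normalized second-channel EV counts"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ev_cohort <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$group, y = .data$ctcs_per_ml)
  ) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::stat_summary(
      fun = stats::median, geom = "crossbar",
      width = 0.4, linewidth = 0.3
    ) +
    ggplot2::labs(
      x = NULL, y = "CTCs / mL",
      title = "Cohort CTC enumeration"
    ) +
    ggplot2::theme_minimal()
}
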