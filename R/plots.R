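#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a binned size distribution in log-log coordinates
#'
#' @param object a [log_bin()] result.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot size_distribution
#' @export
autoplot.size_distribution <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$density > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_center, .data$density)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cluster size (voxels)",
                  y = "probability density (per voxel)") +
    ggplot2::theme_minimal()
}

#' Overlay a power-law fit on its distribution
#'
#' @param dist the [log_bin()] result the fit was computed from.
#' @param fit a [fit_powerlaw()] result.
#' @return a ggplot.
#' @export
plot_powerlaw_fit <- function(dist, fit) {
  stopifnot(inherits(fit, "powerlaw_fit"))
  p <- autoplot.size_distribution(dist)
  tail <- dplyr::filter(tibble::as_tibble(dist),
                        .data$density > 0, .data$bin_center >= fit$s_min_fit)
  # reconstruct the fitted line through the tail's centroid in log space
  lx <- log(tail$bin_center); ly <- log(tail$density)
  intercept <- mean(ly) + fit$alpha * mean(lx)
  tail$fitted <- exp(intercept - fit$alpha * log(tail$bin_center))
  p + ggplot2::geom_line(
    data = tail,
    ggplot2::aes(.data$bin_center, .data$fitted),
    colour = "firebrick") +
    ggplot2::labs(subtitle = sprintf("alpha = %.2f, R² = %.3f",
                                     fit$alpha, fit$r_squared))
}

#' Group trajectories of an HRC metric across thresholds
#'
#' Mean +/- SD of the before-after difference per group and threshold.
#'
#' @param stats_input long table with `participant_id`, `group`,
#'   `timepoint`, `threshold` and the metric.
#' @param metric metric column name.
#' @return a ggplot.
#' @export
plot_threshold_profile <- function(stats_input, metric) {
  d <- stats_input |>
    dplyr::group_by(.data$participant_id, .data$group, .data$threshold) |>
    dplyr::summarise(diff = difference_or_na(.data[[metric]],
                                             .data$timepoint),
                     .groups = "drop") |>
    dplyr::group_by(.data$group, .data$threshold) |>
    dplyr::summarise(m = mean(.data$diff), s = sd(.data$diff),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$threshold), .data$m,
                                  group = .data$group,
                                  colour = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$m - .data$s, ymax = .data$m + .data$s),
      width = 0.2, position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.3)) +
    ggplot2::labs(x = "ReHo threshold (top fraction)",
                  y = sprintf("follow-up minus baseline %s", metric)) +
    ggplot2::theme_minimal()
}
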