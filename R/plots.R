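## ggplot2 helpers for the main result types.

#' Plot trajectories colored by state
#'
#' @param traj trajectory tibble (`x`, `y`, plus `particle` or `traj`,
#'   optionally `state`).
#' @param environment optional circle tibble (`x`, `y`, `r`) to underlay.
#' @return a ggplot.
#' @export
plot_trajectories <- function(traj, environment = NULL) {
  id <- if ("traj" %in% names(traj)) "traj" else "particle"
  p <- ggplot2::ggplot(traj, ggplot2::aes(.data$x, .data$y, group = .data[[id]]))
  if (!is.null(environment) && nrow(environment) > 0) {
    circ <- purrr::map_dfr(seq_len(nrow(environment)), function(i) {
      th <- seq(0, 2 * pi, length.out = 90)
      tibble::tibble(
        cx = environment$x[i] + environment$r[i] * cos(th),
        cy = environment$y[i] + environment$r[i] * sin(th),
        id = i
      )
    })
    p <- p + ggplot2::geom_path(
      data = circ,
      ggplot2::aes(.data$cx, .data$cy, group = .data$id),
      inherit.aes = FALSE, color = "grey60"
    )
  }
  if ("state" %in% names(traj)) {
    p <- p + ggplot2::geom_path(ggplot2::aes(color = factor(.data$state)),
      linewidth = 0.3
    ) +
      ggplot2::labs(color = "state")
  } else {
    p <- p + ggplot2::geom_path(linewidth = 0.3)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.msd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lag, .data$msd)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "lag (frames)", y = expression(MSD ~ (px^2)),
      title = "Time-averaged MSD"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an experiment: trajectories over the environment
#'
#' @param x an `fbm_experiment`.
#' @param ... unused.
#' @return a ggplot.
#' @export
plot.fbm_experiment <- function(x, ...) {
  plot_trajectories(x$trajectories, x$environment)
}

#' Plot predicted vs ground-truth mixture distributions
#'
#' @param truth,pred mixtures (`weight`, `mean`, `sd`).
#' @param support `"alpha"` or `"K"`.
#' @return a ggplot of the two CDFs; the area between them is the W1
#'   distance.
#' @export
plot_mixture_cdf <- function(truth, pred, support = c("alpha", "K")) {
  support <- match.arg(support)
  x <- w1_grid(support)$x
  d <- dplyr::bind_rows(
    tibble::tibble(x = x, cdf = mixture_cdf(truth, x), which = "truth"),
    tibble::tibble(x = x, cdf = mixture_cdf(pred, x), which = "prediction")
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$cdf, color = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = support, y = "CDF", color = NULL) +
    ggplot2::theme_minimal()
  if (support == "K") p <- p + ggplot2::scale_x_log10()
  p
}
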