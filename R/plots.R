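#' Plot a path curve
#'
#' Shows the curve projected onto its two largest-variance coordinate
#' pairs (the first two dimensions for toy systems), with the fitted
#' nodes' parameters marked along it.
#'
#' @param object a `"path_curve"`.
#' @param dims length-2 integer: which coordinates to plot.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot path_curve
#' @export
autoplot.path_curve <- function(object, dims = c(1L, 2L), ...) {
  ag <- seq(0, 1, length.out = 401)
  pts <- path_eval(object, ag)
  df <- tibble(alpha = ag, x = pts[, dims[1]], y = pts[, dims[2]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   color = .data$alpha)) +
    ggplot2::geom_path() +
    ggplot2::scale_color_viridis_c() +
    ggplot2::labs(x = sprintf("coordinate %d", dims[1]),
                  y = sprintf("coordinate %d", dims[2]),
                  color = expression(alpha))
}

#' Plot a replica-exchange run
#'
#' Swap acceptance fraction per adjacent-window pair: flat, high
#' acceptance indicates well-overlapping windows; a collapsed pair marks
#' a sampling bottleneck.
#'
#' @param object an `"hrex_run"`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot hrex_run
#' @export
autoplot.hrex_run <- function(object, ...) {
  df <- object$exchange_log |>
    dplyr::group_by(.data$window_i) |>
    dplyr::summarise(acceptance = mean(.data$accepted), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window_i, y = .data$acceptance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "window pair (i, i+1)", y = "swap acceptance")
}

#' Plot a projection time series
#'
#' @param ts tibble from [projection_timeseries()].
#' @return a ggplot of alpha versus time (or frame).
#' @export
plot_projection <- function(ts) {
  xvar <- if (all(is.finite(ts$time))) "time" else "frame"
  ggplot2::ggplot(ts, ggplot2::aes(x = .data[[xvar]], y = .data$alpha)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = xvar, y = expression(alpha))
}
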