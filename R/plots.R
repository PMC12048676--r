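# ggplot2 autoplot methods for the main result types.

#' Plot an MSD curve
#'
#' @param object an [msd_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot msd_curve
#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$msd)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "Lag time (s)", y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_minimal()
}

#' Plot a dwell-time survival curve
#'
#' @param object a [survival_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot survival_curve
#' @export
autoplot.survival_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time after membrane recruitment (s)",
                  y = "Survival fraction") +
    ggplot2::theme_minimal()
}

#' Plot a patterning-index time series
#'
#' @param object a [patterning_index()] series.
#' @param normalized plot `normalized_pi` if present.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot patterning_series
#' @export
autoplot.patterning_series <- function(object, normalized = FALSE, ...) {
  ycol <- if (normalized && "normalized_pi" %in% names(object)) {
    "normalized_pi"
  } else "pi"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data[[ycol]])) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", alpha = 0.5) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time (s)",
                  y = if (ycol == "pi") {
                    expression(PI == "<" * I["in"] * ">" / "<" * I["out"] * ">")
                  } else "Normalized PI") +
    ggplot2::theme_minimal()
}

#' Plot a radial wound kymograph
#'
#' @param object a [radial_kymograph()].
#' @param ... unused.
#' @return a ggplot (distance x time heat map).
#' @method autoplot radial_kymograph
#' @export
autoplot.radial_kymograph <- function(object, ...) {
  df <- expand.grid(distance = object$distance, time = object$time)
  df$intensity <- as.vector(object$intensity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$distance,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "Intensity (a.u.)") +
    ggplot2::labs(x = "Time (s)", y = "Distance from wound (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a colocalization probability-by-position profile
#'
#' @param df output of [coloc_probability_by_position()].
#' @param chance optional horizontal chance level
#'   ([chance_colocalization()]).
#' @return a ggplot.
#' @export
plot_coloc_probability <- function(df, chance = NULL) {
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frame_offset,
                                        y = .data$probability)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$probability - .data$sd, 0),
                                      ymax = pmin(.data$probability + .data$sd, 1)),
                         alpha = 0.3) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Frames since membrane recruitment",
                  y = "Colocalization probability") +
    ggplot2::theme_minimal()
  if (!is.null(chance)) {
    p <- p + ggplot2::geom_hline(yintercept = chance, linetype = "dashed")
  }
  p
}
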