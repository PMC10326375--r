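#' Plot detected particles over intensity summaries
#'
#' @param object An `agg_particles` tibble from [detect_spots()].
#' @param ... Unused.
#' @return A ggplot: particle positions sized by integrated intensity.
#' @export
autoplot.agg_particles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x_px, .data$y_px,
                                       size = .data$integrated_intensity)) +
    ggplot2::geom_point(alpha = 0.6, colour = "#2166ac") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", size = "Integrated\nintensity",
                  title = sprintf("%d detected particles",
                                  attr(object, "n_particles"))) +
    ggplot2::theme_minimal()
}

#' Plot the per-liposome influx distribution
#'
#' @param object An `agg_influx` tibble.
#' @param ... Unused.
#' @return A ggplot: histogram of valid per-liposome influx percentages with
#'   the median marked.
#' @export
autoplot.agg_influx <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), .data$valid)
  ggplot2::ggplot(d, ggplot2::aes(.data$influx_percent)) +
    ggplot2::geom_histogram(bins = 40, fill = "#4393c3", colour = "white") +
    ggplot2::geom_vline(xintercept = median(d$influx_percent),
                        linetype = 2) +
    ggplot2::labs(x = "Calcium influx (%)", y = "Liposomes",
                  title = sprintf("Median influx %.1f%%",
                                  median(d$influx_percent))) +
    ggplot2::theme_minimal()
}

#' Plot cluster morphometrics
#'
#' @param object An `agg_clusters` tibble.
#' @param ... Unused.
#' @return A ggplot: aggregate length distribution (nm, log10 x).
#' @export
autoplot.agg_clusters <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$length_nm)) +
    ggplot2::stat_ecdf() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Aggregate length (nm)", y = "Cumulative proportion",
                  title = sprintf("%d aggregates, median length %.0f nm",
                                  nrow(object),
                                  median(object$length_nm))) +
    ggplot2::theme_minimal()
}

#' Plot a counting-accuracy validation table
#'
#' @param validation Output of [validate_counting()].
#' @param by `"snr"` or `"n_dots"` for the x axis.
#' @return A ggplot of mean accuracy per condition.
#' @export
plot_counting_accuracy <- function(validation, by = c("snr", "n_dots")) {
  by <- match.arg(by)
  ggplot2::ggplot(validation,
                  ggplot2::aes(.data[[by]], .data$mean_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_accuracy - .data$sd_accuracy,
      ymax = .data$mean_accuracy + .data$sd_accuracy
    )) +
    ggplot2::labs(x = if (by == "snr") "Signal-to-noise ratio" else
      "Particles per FOV", y = "Counting accuracy (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname cluster_localizations
#' @export
tidy.agg_clusters <- function(x, ...) as_tibble(x)

#' @rdname detect_spots
#' @export
tidy.agg_particles <- function(x, ...) as_tibble(x)

#' @rdname measure_influx
#' @export
tidy.agg_influx <- function(x, ...) as_tibble(x)
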