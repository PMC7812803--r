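# ggplot2 views of the result types.

#' Plot a census time course
#'
#' Replicate censuses are aggregated to mean and SD; the mean is drawn as a
#' line with an SD ribbon, one panel per population.
#'
#' @param object A `gc_timecourse`.
#' @param populations Which populations to show (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gc_timecourse
#' @export
autoplot.gc_timecourse <- function(object, populations = NULL, ...) {
  agg <- aggregate_timecourse(object)
  if (!is.null(populations))
    agg <- dplyr::filter(agg, .data$population %in% populations)
  agg$sd[is.na(agg$sd)] <- 0
  ggplot2::ggplot(agg, ggplot2::aes(.data$time_h / 24, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$population), scales = "free_y") +
    ggplot2::labs(x = "day", y = "cells")
}

#' @export
plot.gc_timecourse <- function(x, ...) print(autoplot.gc_timecourse(x, ...))

#' Plot the RSS landscape of a grid fit
#'
#' One point per evaluated grid point, faceted by parameter.
#'
#' @param object A `gc_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gc_fit
#' @export
autoplot.gc_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$grid_results,
                              -dplyr::all_of("rss"),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$rss)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free_x") +
    ggplot2::labs(x = "parameter value", y = "RSS",
                  title = paste0(object$topology, " (best RSS ",
                                 signif(object$rss, 4), ")"))
}

#' Plot a CTV composition table
#'
#' Stacked shares of the cMyc+ subpopulations per division compartment.
#'
#' @param composition Output of [ctv_composition()] (or the packaged
#'   reference table).
#' @return A ggplot.
#' @export
plot_ctv_composition <- function(composition) {
  comp <- dplyr::filter(tibble::as_tibble(composition),
                        !is.na(.data$percent))
  ggplot2::ggplot(comp, ggplot2::aes(.data$compartment, .data$percent,
                                     fill = .data$subpop)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "CTV division compartment",
                  y = "% of cMyc+ cells in compartment", fill = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
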