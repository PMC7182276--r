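#' Plot methods
#'
#' `autoplot()` methods returning ggplot objects for the package's main
#' result types: waveforms, transduction trajectories, rate histograms,
#' steady-rate maps, population responses and fitted encoding manifolds.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name flyosn-autoplot
NULL

#' @rdname flyosn-autoplot
#' @export
autoplot.odor_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$u)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "concentration (ppm)",
                  title = paste0(attr(object, "family"), " waveform"))
}

#' @rdname flyosn-autoplot
#' @export
autoplot.otp_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object, -"t", names_to = "state",
                              values_to = "value")
  long$state <- factor(long$state, levels = c("v", "x1", "x2", "x3", "I"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~state, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "transduction cascade trajectory")
}

#' @rdname flyosn-autoplot
#' @export
autoplot.psth <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$rate)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (s)", y = "rate (spikes/s)")
}

#' @rdname flyosn-autoplot
#' @export
autoplot.rate_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$product, y = .data$rate)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "affinity x amplitude", y = "settled rate (spikes/s)")
}

#' @rdname flyosn-autoplot
#' @export
autoplot.population_psth <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$group,
                                       fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "rate (spikes/s)") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "population response")
}

#' @rdname flyosn-autoplot
#' @export
autoplot.osn_manifold <- function(object, ...) {
  g <- manifold_grid(object, object$u_range, object$dudt_range)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$u, y = .data$dudt,
                                  z = .data$rate)) +
    ggplot2::geom_contour_filled() +
    ggplot2::labs(x = "concentration (ppm)",
                  y = "concentration gradient (ppm/s)",
                  title = "2D encoding manifold")
}

#' @rdname flyosn-autoplot
#' @export
autoplot.osn_fit <- function(object, ...) {
  d <- tibble::tibble(generation = seq_along(object$trace),
                      loss = object$trace)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$generation, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "best loss")
}

#' @export
tidy.osn_fit <- function(x, ...) {
  tibble::tibble(term = names(x$values), estimate = unname(x$values))
}

#' @export
glance.osn_fit <- function(x, ...) {
  tibble::tibble(loss = x$loss, generations = length(x$trace),
                 evaluations = x$evaluations)
}
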