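#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_step labs scale_fill_viridis_c theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot an energy landscape
#'
#' Minimized loop energy as a function of length and register angle.
#'
#' @param object An [energy_landscape()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.energy_landscape <- function(object, ...) {
  ggplot(object, aes(x = .data$length_bp, y = .data$theta_rad,
                     fill = .data$energy_kT)) +
    geom_tile() +
    scale_fill_viridis_c(name = "E_bend (kT)") +
    labs(x = "length (bp)", y = expression(Theta ~ "(rad)")) +
    theme_minimal()
}

#' Plot a looping-rate profile
#'
#' Relative looping rate versus length on a log scale.
#'
#' @param object A [looping_rate_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rate_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$length_bp, y = log(.data$k_rel))) +
    geom_line() +
    geom_point() +
    labs(x = "length (bp)", y = "log k_loop (relative)") +
    theme_minimal()
}

#' Plot a periodogram
#'
#' @param object An [oscillation_period()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.oscillation_fit <- function(object, ...) {
  ggplot(object$periodogram, aes(x = .data$period_bp, y = .data$power)) +
    geom_line() +
    labs(x = "period (bp)", y = expression(R^2),
         title = sprintf("dominant period %.1f bp", object$period_bp)) +
    theme_minimal()
}

#' Plot a joint end-angle distribution
#'
#' @param object An [end_angle_distribution()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.angle_distribution <- function(object, ...) {
  e1 <- object$theta1_edges
  mids <- (e1[-1] + e1[-length(e1)]) / 2
  d <- tidyr::expand_grid(theta1 = mids, theta2 = mids)
  d$p <- as.vector(t(object$density))
  ggplot(d, aes(x = .data$theta1, y = .data$theta2, fill = .data$p)) +
    geom_tile() +
    scale_fill_viridis_c(name = "P") +
    labs(x = expression(theta[1] ~ "(rad)"), y = expression(theta[2] ~ "(rad)")) +
    theme_minimal()
}

#' Plot FRET traces
#'
#' Donor and acceptor intensities over time for a few traces.
#'
#' @param object A [generate_traces()] tibble.
#' @param traces Trace ids to show (default: first 3).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fret_traces <- function(object, traces = NULL, ...) {
  ids <- traces %||% utils::head(unique(object$trace_id), 3)
  d <- object |>
    dplyr::filter(.data$trace_id %in% ids) |>
    tidyr::pivot_longer(c("donor", "acceptor"), names_to = "channel",
                        values_to = "intensity")
  ggplot(d, aes(x = .data$time_s, y = .data$intensity,
                colour = .data$channel)) +
    geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(donor = "#2ca25f",
                                            acceptor = "#de2d26")) +
    facet_wrap(~trace_id, ncol = 1) +
    labs(x = "time (s)", y = "intensity (counts)") +
    theme_minimal()
}

#' Plot a survival (decay) curve with its exponential fit
#'
#' @param samples An `fpt_sample` tibble.
#' @param fit Optional `rate_fit` whose exponential is overlaid.
#' @return A ggplot.
#' @export
plot_survival <- function(samples, fit = NULL) {
  km <- survival_curve(samples)
  p <- ggplot(km, aes(x = .data$time_s, y = .data$survival)) +
    geom_step() +
    labs(x = "time since exchange (s)", y = "surviving fraction") +
    theme_minimal()
  if (!is.null(fit)) {
    grid <- tibble::tibble(time_s = seq(0, max(km$time_s), length.out = 200))
    grid$survival <- exp(-fit$rate * grid$time_s)
    p <- p + geom_line(data = grid, colour = "red")
  }
  p
}
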