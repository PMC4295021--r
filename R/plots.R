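# ggplot2 views of the main result types.

#' Plot a rate-vs-temperature curve
#'
#' Mean rates with the replicate min-max envelope, one panel style per
#' amendment when several are present.
#'
#' @param curve Aggregated rate tibble from [aggregate_replicates()].
#' @return A ggplot object.
#' @export
plot_rate_curve <- function(curve) {
  cv <- as_tibble(curve)
  p <- ggplot2::ggplot(cv, ggplot2::aes(x = .data$temperature_C,
                                        y = .data$rate_nmol_ml_d))
  if (all(c("rate_min", "rate_max") %in% names(cv)))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$rate_min, ymax = .data$rate_max),
      fill = "grey80")
  if ("amendment" %in% names(cv) && length(unique(cv$amendment)) > 1L)
    p <- p + ggplot2::aes(colour = .data$amendment)
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Temperature (°C)",
                  y = expression(SRR~(nmol~ml^-1~d^-1)))
}

#' Plot energy density versus temperature
#'
#' @param energy Tibble from [energy_density_curve()] (possibly several
#'   boreholes).
#' @return A ggplot object.
#' @export
plot_energy_density <- function(energy) {
  ggplot2::ggplot(as_tibble(energy),
                  ggplot2::aes(x = .data$temperature_C,
                               y = .data$energy_density_J_kg,
                               colour = .data$borehole)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Temperature (°C)",
                  y = expression(Energy~density~(J~kg^-1~fluid)))
}

#' @export
#' @method autoplot standard_curve
autoplot.standard_curve <- function(object, ...) {
  d <- object$fit$model
  names(d) <- c("cq", "log10_copies")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log10_copies, y = .data$cq)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept, colour = "grey40") +
    ggplot2::labs(x = expression(log[10]~copies~per~reaction),
                  y = "Cq (cycles)",
                  subtitle = sprintf("slope %.3f, efficiency %.3f, r² %.4f",
                                     object$slope, object$efficiency,
                                     object$r_squared))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
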