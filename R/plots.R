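#' Plot a MAP fit: observations against individual and typical predictions
#'
#' @param object A `vanco_map` object from [map_fit()].
#' @param dt Curve grid spacing, h.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vanco_map <- function(object, dt = 0.25, ...) {
  reg <- object$regimen
  t_end <- max(reg$start_time + reg$duration + 24, object$obs$time)
  grid <- seq(0, t_end, by = dt)
  ip0 <- individual_params(object$patient, object$params)
  curves <- dplyr::bind_rows(
    dplyr::mutate(predict_conc(object$individual, reg, grid),
                  curve = "individual (MAP)"),
    dplyr::mutate(predict_conc(ip0[, c("cl", "v1", "q", "v2")], reg, grid),
                  curve = "typical (eta = 0)")
  )
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$conc)) +
    ggplot2::geom_line(ggplot2::aes(linetype = .data$curve)) +
    ggplot2::geom_point(data = object$obs, colour = "firebrick", size = 2) +
    ggplot2::labs(x = "Time since first dose (h)",
                  y = "Vancomycin concentration (mg/L)",
                  linetype = NULL, title = "MAP empirical-Bayes fit") +
    ggplot2::theme_minimal()
}

#' Overlay simulated scenario groups
#'
#' Convenience layer over several [simulate_population()] results: medians
#' with 90% prediction-interval ribbons, one facet per scenario.
#'
#' @param sims A list of `vanco_sim` objects.
#' @return A ggplot.
#' @export
plot_scenarios <- function(sims) {
  dat <- purrr::map_dfr(sims, function(s) {
    dplyr::mutate(s$profiles,
                  label = if (!is.na(s$label)) s$label else "scenario")
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "Time (h)",
                  y = "Vancomycin concentration (mg/L)") +
    ggplot2::theme_minimal()
}
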