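#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot predictive trajectory bands
#'
#' Median line with nested 68% (dark) and 95% (light) equal-tailed ribbons
#' per day, the conventional display for forward trajectory uncertainty.
#'
#' @param object An `ideatraj_prediction`.
#' @param observations Optional tibble (`time_days`, `sidas_total`) of
#'   realised observations to overlay, with day 0 at the prediction origin.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ideatraj_prediction <- function(object, observations = NULL, ...) {
  d <- object$daily
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$day)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$eti95_lo,
                                      ymax = .data$eti95_hi),
                         fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$eti68_lo,
                                      ymax = .data$eti68_hi),
                         fill = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), linewidth = 0.8) +
    ggplot2::labs(
      x = "Days ahead", y = "SIDAS total",
      subtitle = sprintf("IHIP %.2f | FUT %d d%s | V %.1f", object$ihip,
                         object$fut_days,
                         if (object$fut_censored) " (censored)" else "",
                         object$v)
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 50)) +
    ggplot2::theme_minimal()
  if (!is.null(observations)) {
    p <- p + ggplot2::geom_point(
      data = observations,
      ggplot2::aes(x = .data$time_days, y = .data$sidas_total),
      colour = "red3"
    )
  }
  p
}

#' Plot population posterior distributions of a fit
#'
#' Density of each population-level draw column (means, SDs, fixed effects).
#'
#' @param object An `ideatraj_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ideatraj_fit <- function(object, ...) {
  keep <- colnames(object$pop_draws)
  if (!object$config$estimate_sigma_y) keep <- setdiff(keep, "sigma_y")
  long <- tibble::tibble(
    parameter = rep(keep, each = nrow(object$pop_draws)),
    value = as.vector(object$pop_draws[, keep])
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "Posterior density") +
    ggplot2::theme_minimal()
}

#' Spaghetti plot of a cohort's observed trajectories
#'
#' @param object An `ideatraj_cohort`.
#' @param max_individuals Cap on plotted individuals (first by id).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ideatraj_cohort <- function(object, max_individuals = 30, ...) {
  ids <- utils::head(unique(object$data$individual_id), max_individuals)
  d <- object$data[object$data$individual_id %in% ids, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_days, y = .data$sidas_total,
                                  group = .data$individual_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::labs(x = "Days since baseline", y = "SIDAS total") +
    ggplot2::theme_minimal()
}
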