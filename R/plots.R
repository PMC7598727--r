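# ggplot2 quick-look plots for the main result types.

#' Plot monomer and cluster kinetic curves
#'
#' @param curves A kinetic-counts tibble from [kinetic_counts()] or
#'   [simulate_coalescence()]`$curves`.
#' @return A ggplot object.
#' @export
plot_kinetics <- function(curves) {
  long <- dplyr::bind_rows(
    tibble::tibble(time = curves$time, value = curves$n_monomers, series = "monomers"),
    tibble::tibble(time = curves$time, value = curves$n_clusters, series = "clusters"),
    tibble::tibble(time = curves$time, value = curves$largest, series = "largest M")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     color = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "count", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot scaled master curves
#'
#' @param scaled Output of [scale_curves()] (optionally several runs
#'   row-bound with a distinguishing `run` column).
#' @return A ggplot object with logarithmic scaled time.
#' @export
plot_scaled_kinetics <- function(scaled) {
  p <- ggplot2::ggplot(
    dplyr::filter(scaled, .data$t_scaled > 0),
    ggplot2::aes(x = .data$t_scaled, y = .data$value)
  )
  if ("run" %in% names(scaled)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(color = factor(.data$run)))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p +
    ggplot2::facet_wrap(~series, scales = "free") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "scaled time", y = "scaled count", color = "run") +
    ggplot2::theme_minimal()
}

#' Plot a mass-center distance histogram
#'
#' @param hist A histogram tibble from [mass_center_histogram()].
#' @return A ggplot object.
#' @export
plot_distance_histogram <- function(hist) {
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$mid, y = .data$prob)) +
    ggplot2::geom_col(width = hist$bin_hi[1] - hist$bin_lo[1]) +
    ggplot2::labs(x = "mass-center distance (nm)", y = "probability") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Log-log plot of a power-law scaling fit
#'
#' @param object An `ft_power_fit` from [fit_power_small()] or
#'   [fit_power_shifted()].
#' @param ... Ignored.
#' @return A ggplot object showing the fitted points and line in the
#'   fit's log-log coordinates.
#' @method autoplot ft_power_fit
#' @export
autoplot.ft_power_fit <- function(object, ...) {
  d <- object$fit$model
  names(d) <- c("ly", "lx")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lx, y = .data$ly)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$exponent, intercept = object$intercept,
                         color = "red") +
    ggplot2::labs(
      x = if (object$variant == "small") "ln M" else "ln (M - M*)",
      y = if (object$variant == "small") "ln Rg" else "ln (Rg - Rg*)",
      title = sprintf("%s fit: exponent %.3f +/- %.3f", object$variant,
                      object$exponent, object$exponent_se)
    ) +
    ggplot2::theme_minimal()
}

#' Per-ribbon helicity bars of a helicity result
#'
#' @param object An `ft_helicity` from [fibril_helicity()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot ft_helicity
#' @export
autoplot.ft_helicity <- function(object, ...) {
  d <- dplyr::filter(object$ribbons, !is.na(.data$h_rib))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$ribbon), y = .data$h_rib)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$h, linetype = "dashed") +
    ggplot2::labs(x = "ribbon", y = "ribbon helicity",
                  subtitle = sprintf("cluster helicity H = %.4f", object$h)) +
    ggplot2::theme_minimal()
}
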