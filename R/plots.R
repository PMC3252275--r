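#' Log-log CCDF plot of phase-lock interval durations
#'
#' @param pli PLI tibble (from [window_pli()], [extract_pli()] or
#'   [model_pli()]); rows are pooled within each scale (and window, if
#'   `facet_windows`).
#' @param unit Plot `duration_seconds` (default) or `duration_samples`.
#' @param facet_windows Facet by `window_id`? Default `FALSE`.
#' @return A ggplot.
#' @export
plot_pli_ccdf <- function(pli, unit = c("duration_seconds", "duration_samples"),
                          facet_windows = FALSE) {
  unit <- match.arg(unit)
  grp <- if (facet_windows) c("scale", "window_id") else "scale"
  cc <- pli |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::reframe(empirical_ccdf(.data[[unit]]))
  p <- ggplot2::ggplot(cc, ggplot2::aes(.data$value, .data$ccdf,
                                        colour = factor(.data$scale))) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = sprintf("PLI duration (%s)",
                              sub("duration_", "", unit)),
                  y = "P(X ≥ x)", colour = "scale") +
    ggplot2::theme_minimal()
  if (facet_windows) p <- p + ggplot2::facet_wrap(~window_id)
  p
}

#' @export
autoplot.pl_fit <- function(object, ...) {
  cc <- empirical_ccdf(object$x)
  tail_cc <- cc[cc$value >= object$xmin, ]
  scale0 <- tail_cc$ccdf[1]
  fitline <- tibble(
    value = exp(seq(log(object$xmin), log(max(cc$value)), length.out = 50)))
  fitline$ccdf <- scale0 * ppareto_sf(fitline$value, object$alpha, object$xmin)
  ggplot2::ggplot(cc, ggplot2::aes(.data$value, .data$ccdf)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(data = fitline, colour = "red", linetype = 2) +
    ggplot2::geom_vline(xintercept = object$xmin, linetype = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "duration", y = "P(X ≥ x)",
                  title = sprintf("Power-law fit: alpha = %.2f, xmin = %.3g",
                                  object$alpha, object$xmin)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.delta_timecourse <- function(object, ...) {
  xcol <- if ("start_s" %in% names(object)) "start_s" else "window_id"
  ggplot2::ggplot(object, ggplot2::aes(.data[[xcol]], .data$delta,
                                       colour = factor(.data$scale))) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = if (xcol == "start_s") "window start (s)" else "window",
                  y = expression(Delta), colour = "scale") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.soc_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$k_series, ggplot2::aes(.data$iteration, .data$k)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "topology update", y = "mean connectivity K") +
    ggplot2::theme_minimal()
}

#' Frozen-component transition plot
#'
#' @param sweep Tibble from [frozen_sweep()].
#' @return A ggplot of the order parameter against connectivity.
#' @export
plot_frozen_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(.data$k, .data$frozen)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "mean connectivity K", y = "frozen component") +
    ggplot2::theme_minimal()
}
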