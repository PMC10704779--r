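## ggplot2 views of the fitted objects: every plot works from the tables
## the fits already carry, so plotting never recomputes an analysis.

#' Plot a length-weight fit
#'
#' Scatter of the fish with the fitted power-law curve, on natural or
#' log10 axes.
#'
#' @param object An `lwr_fit`.
#' @param log_axes Plot on log10-log10 axes (where the model is a line)?
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lwr_fit <- function(object, log_axes = FALSE, ...) {
  d <- object$data
  grid <- tibble(
    total_length = seq(min(d$total_length), max(d$total_length), length.out = 200)
  )
  grid$body_weight <- object$a * grid$total_length^object$b
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$total_length, y = .data$body_weight)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = "Total length (cm)", y = "Body weight (g)",
      title = sprintf("W = %.4g L^%.3g  (R² = %.3f)", object$a, object$b, object$r_squared)
    ) +
    ggplot2::theme_minimal()
  if (log_axes) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' Plot a von Bertalanffy fit
#'
#' Length-at-age scatter with the fitted growth curve and its asymptote.
#'
#' @param object A `vbgf_fit` (converged).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vbgf_fit <- function(object, ...) {
  d <- object$data
  est <- object$estimate
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$len)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Age (yr)", y = "Total length (cm)",
                  title = sprintf("VBGF [%s]", object$partition_label)) +
    ggplot2::theme_minimal()
  if (all(is.finite(est))) {
    grid <- tibble(age = seq(min(d$age), max(d$age), length.out = 200))
    grid$len <- vbgf_predict(grid$age, est[["L_inf"]], est[["K"]], est[["t0"]])
    p <- p +
      ggplot2::geom_line(data = grid, colour = "steelblue", linewidth = 0.8) +
      ggplot2::geom_hline(yintercept = est[["L_inf"]], linetype = "dashed",
                          colour = "grey50")
  }
  p
}

#' Auximetric plot of species growth parameters
#'
#' log10 K against log10 L-infinity per species, coloured by group, with
#' each group's slope -2 iso-performance contour.
#'
#' @param aux An [auximetric_table()] output.
#' @param iso_lines Draw per-group mean phi-prime contours?
#' @return A ggplot.
#' @export
plot_auximetric <- function(aux, iso_lines = TRUE) {
  p <- ggplot2::ggplot(aux, ggplot2::aes(x = .data$log10_L_inf, y = .data$log10_K,
                                         colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression(log[10] ~ L[infinity]),
      y = expression(log[10] ~ K),
      colour = "Group"
    ) +
    ggplot2::theme_minimal()
  if (iso_lines) {
    iso <- phi_iso_lines(aux)
    p <- p + ggplot2::geom_abline(
      data = iso,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$group),
      linetype = "dotted"
    )
  }
  p
}
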