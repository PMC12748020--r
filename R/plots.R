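#' Plot a decay signal
#'
#' ROI-mean signal against b-value on a log intensity scale, the standard
#' way IVIM decay curves are displayed.
#'
#' @param decay A decay-signal tibble.
#' @return A ggplot object.
#' @export
plot_decay <- function(decay) {
  check_decay(decay)
  ggplot2::ggplot(decay, ggplot2::aes(x = .data$b, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(b ~ (s/mm^2)), y = "signal (log scale)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.yi_fit
#' @method autoplot ivim_fit
#' @export
autoplot.ivim_fit <- function(object, ...) {
  dat <- object$decay
  grid <- tibble::tibble(b = seq(min(dat$b), max(dat$b), length.out = 200))
  grid$signal <- predict(object, grid$b)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$b, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(b ~ (s/mm^2)), y = "signal (log scale)",
      title = sprintf("%s bi-exponential fit from b = %g", object$method,
                      object$b_start),
      subtitle = sprintf("pf_i = %.3f, d_slow = %.3g, d_fast = %.3g mm^2/s",
                         object$pf_i, object$d_slow, object$d_fast)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted log-odds line
#'
#' Shows the per-starting-b log-odds values, the fitted line over the grid
#' points, and (hollow) any diagnostic points excluded from the fit — the
#' b = 0 point typically falls well below the line when a very fast
#' perfusion component is present.
#'
#' @param object A `yi_fit` (or `ivim_fit`) object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot yi_fit
#' @export
autoplot.yi_fit <- function(object, ...) {
  if (is.null(object$regression)) {
    stop("autoplot.yi_fit: no fitted line to plot", call. = FALSE)
  }
  pts <- object$regression$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$b_i, y = .data$y_i)) +
    ggplot2::geom_abline(slope = object$regression$slope,
                         intercept = object$regression$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$used_in_fit), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "in line fit") +
    ggplot2::labs(
      x = expression(b[i] ~ (s/mm^2)),
      y = expression(Y[i] == ln((1 - PF[i]) / PF[i])),
      title = sprintf("log-odds line: slope = %.3g, R^2 = %.3f",
                      object$regression$slope, object$regression$r_squared)) +
    ggplot2::theme_minimal()
}
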