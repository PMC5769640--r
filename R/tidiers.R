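# broom-style accessors and ggplot2 methods for simulation results

#' Per-step force record of a run
#'
#' @param x a `flap_run`.
#' @param ... unused.
#' @return tibble with `t`, `tau`, `Fx`, `Fy`, `CL`, `CD`.
#' @export
tidy.flap_run <- function(x, ...) x$forces

#' One-row summary of a run
#'
#' Mean CL and CD over the case's record window, the RMS of each trace,
#' reference speed, penalization scale and step count.
#'
#' @param x a `flap_run`.
#' @param ... unused.
#' @export
glance.flap_run <- function(x, ...) {
  w <- x$case$record_window
  m <- time_average(x$forces, c("CL", "CD"), w)
  tibble(case = x$case$profile$name,
         boundary_mode = x$case$boundary_mode,
         V_inf = x$case$V_inf,
         mean_CL = m$CL, mean_CD = m$CD,
         tau_lo = w[1], tau_hi = w[2],
         V_mag = x$V_mag, eta = x$eta, steps = x$steps)
}

#' @export
autoplot.flap_run <- function(object, cols = c("CL", "CD"), ...) {
  d <- tidyr::pivot_longer(object$forces[, c("tau", cols)],
                           dplyr::all_of(cols),
                           names_to = "coefficient", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tau, y = .data$value,
                                  colour = .data$coefficient)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(tau), y = NULL,
                  title = sprintf("%s (%s)", object$case$profile$name,
                                  object$case$boundary_mode))
}

#' Vorticity contour plot of a flow state
#'
#' @param state a `flow_state`.
#' @param limits symmetric colour limits in 1/s (default from the field).
#' @export
plot_vorticity <- function(state, limits = NULL) {
  g <- state$grid
  w <- vorticity(state)
  d <- expand.grid(x = (0:g$nx) * g$dx, y = (0:g$ny) * g$dy)
  d$w <- as.vector(w)
  if (is.null(limits)) limits <- c(-1, 1) * stats::quantile(abs(d$w), 0.99)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$w)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = limits, oob = scales_squish) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "vorticity (1/s)")
}

# minimal squish so we avoid a scales dependency
scales_squish <- function(x, range = c(0, 1), ...) {
  pmin(pmax(x, range[1]), range[2])
}
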