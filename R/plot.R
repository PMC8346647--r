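#' Plot a rate curve
#'
#' @param x a [rate_curve()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.rate_curve <- function(x, ...) {
  graphics::plot(kelvin_to_celsius(x$temperature), x$rate, type = "l",
                 xlab = expression("Temperature (" * degree * "C)"),
                 ylab = expression(dx / dT ~ (K^-1)), ...)
  invisible(x)
}

#' Plot a DAEM fit: data, fitted mixture, per-component curves
#'
#' Experimental points, the fitted mixture line, and dashed per-component
#' contributions (deconvolution display).
#'
#' @param x a `fit_result`.
#' @param data optional [rate_curve()] (or list of replicates) to overlay
#'   as points.
#' @param every plot every n-th data point to keep the cloud readable.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fit_result <- function(x, data = NULL, every = 5, ...) {
  comps <- x$per_component_curves
  mix_t <- comps[[1]]$temperature
  mix <- Reduce(`+`, lapply(comps, `[[`, "rate"))
  ylim <- c(0, max(mix, if (!is.null(data)) {
    if (inherits(data, "rate_curve")) data$rate else unlist(lapply(data, `[[`, "rate"))
  }))
  graphics::plot(kelvin_to_celsius(mix_t), mix, type = "n", ylim = ylim,
                 xlab = expression("Temperature (" * degree * "C)"),
                 ylab = expression(dx / dT ~ (K^-1)), ...)
  if (!is.null(data)) {
    if (inherits(data, "rate_curve")) data <- list(data)
    for (d in data) {
      keep <- seq(1, length(d$temperature), by = every)
      graphics::points(kelvin_to_celsius(d$temperature[keep]), d$rate[keep],
                       pch = 1, cex = 0.5, col = "grey40")
    }
  }
  for (i in seq_along(comps))
    graphics::lines(kelvin_to_celsius(comps[[i]]$temperature),
                    comps[[i]]$rate, lty = 2, col = i + 1)
  graphics::lines(kelvin_to_celsius(mix_t), mix, lwd = 2)
  graphics::legend("topright", bty = "n",
                   legend = c("fit", sprintf("component %d", seq_along(comps))),
                   lwd = c(2, rep(1, length(comps))),
                   lty = c(1, rep(2, length(comps))),
                   col = c(1, seq_along(comps) + 1))
  invisible(x)
}
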