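## Raw thermogram -> analysis-ready DTG / DSC-derivative curves.
##
## Order of operations matters: smooth the raw mass and heat-flow channels
## once (mild Savitzky-Golay), normalize mass to conversion inside the
## analysis window, differentiate with respect to temperature, truncate to
## the window. Aggressive filtering can conceal minor DTG peaks, so the
## defaults are mild and the filter is never applied twice.

#' TGA/DSC thermogram
#'
#' Container for one run's raw channels. Sign convention for heat flow:
#' exothermic positive, endothermic negative.
#'
#' @param time seconds.
#' @param temperature K, non-decreasing.
#' @param mass mg, strictly positive.
#' @param heat_flow mW, signed (exothermic positive).
#' @param replicate_id label for replicate bookkeeping.
#' @return Object of class `thermogram`.
#' @export
thermogram <- function(time, temperature, mass, heat_flow,
                       replicate_id = "r1") {
  n <- length(temperature)
  if (n < 10) .stopf("thermogram needs at least 10 points")
  if (length(time) != n || length(mass) != n || length(heat_flow) != n)
    .stopf("thermogram channels must have equal length")
  if (any(diff(temperature) < 0)) .stopf("temperature must be non-decreasing")
  if (any(mass <= 0)) .stopf("mass must stay positive")
  structure(list(time = as.numeric(time), temperature = as.numeric(temperature),
                 mass = as.numeric(mass), heat_flow = as.numeric(heat_flow),
                 replicate_id = as.character(replicate_id)),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram> %s: %d points, %.1f-%.1f C, mass %.2f -> %.2f mg\n",
              x$replicate_id, length(x$time),
              kelvin_to_celsius(min(x$temperature)),
              kelvin_to_celsius(max(x$temperature)),
              x$mass[1], x$mass[length(x$mass)]))
  invisible(x)
}

#' @export
as.data.frame.thermogram <- function(x, ...) {
  data.frame(time = x$time, temperature = x$temperature,
             mass = x$mass, heat_flow = x$heat_flow,
             replicate_id = x$replicate_id)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing (via [signal::sgolayfilt()]),
#' which reproduces polynomials up to the filter order exactly, including
#' at the series ends where one-sided windows are used.
#'
#' @param series numeric values on a uniform grid.
#' @param window odd window length, > `order` and <= `length(series)`.
#' @param order polynomial degree.
#' @return Smoothed series of the same length.
#' @export
savitzky_golay <- function(series, window = 21, order = 3) {
  if (window %% 2 == 0) .stopf("window must be odd")
  if (window <= order) .stopf("window must exceed the polynomial order")
  if (window > length(series)) .stopf("window exceeds series length")
  as.numeric(signal::sgolayfilt(series, p = order, n = window))
}

#' Conversion degree from the mass channel
#'
#' x = (m0 - m) / (m0 - m_inf), with m0 and m_inf the masses at the start
#' and end of the analysis window (linearly interpolated from the trace),
#' so pre-window moisture loss is excluded from the conversion scale.
#'
#' @param tg a [thermogram()] (smooth the mass channel first).
#' @param window analysis window `c(t_lo, t_hi)`, K; defaults to 200-600 C.
#' @return Conversion values on the thermogram's own grid. Numerical
#'   excursions beyond \[0, 1\] smaller than 1e-6 are clipped; larger ones
#'   (e.g. pre-window moisture loss) are left visible.
#' @export
conversion_from_mass <- function(tg, window = c(celsius_to_kelvin(200),
                                                celsius_to_kelvin(600))) {
  stopifnot(inherits(tg, "thermogram"))
  rng <- range(tg$temperature)
  if (window[1] < rng[1] - 1e-6 || window[2] > rng[2] + 1e-6)
    .stopf("analysis window [%.2f, %.2f] K outside data range [%.2f, %.2f] K",
           window[1], window[2], rng[1], rng[2])
  m0 <- stats::approx(tg$temperature, tg$mass, xout = window[1], ties = mean)$y
  m_inf <- stats::approx(tg$temperature, tg$mass, xout = window[2], ties = mean)$y
  if (abs(m0 - m_inf) < .Machine$double.eps * max(m0, 1))
    .stopf("no mass loss inside the window (m0 = m_inf): degenerate sample")
  x <- (m0 - tg$mass) / (m0 - m_inf)
  x[x < 0 & x > -1e-6] <- 0
  x[x > 1 & x < 1 + 1e-6] <- 1
  x
}

#' Derivative with respect to temperature
#'
#' Central finite differences on a possibly non-uniform grid (second-order
#' three-point formula), one-sided at the ends. Exact duplicates in the
#' grid are collapsed by averaging before differencing.
#'
#' @param series values.
#' @param temperature grid, K; must be strictly increasing after
#'   de-duplication.
#' @param dedup_tol temperatures closer than this are treated as duplicates.
#' @return List with `temperature` (de-duplicated grid) and `derivative`.
#' @export
derivative_wrt_temperature <- function(series, temperature, dedup_tol = 1e-9) {
  if (length(series) != length(temperature)) .stopf("lengths differ")
  ## collapse duplicate temperatures by averaging the values
  grp <- cumsum(c(TRUE, abs(diff(temperature)) > dedup_tol))
  if (max(grp) < length(temperature)) {
    temperature <- as.numeric(tapply(temperature, grp, mean))
    series <- as.numeric(tapply(series, grp, mean))
  }
  if (any(diff(temperature) <= 0))
    .stopf("temperature grid not strictly increasing after de-duplication")
  n <- length(temperature)
  if (n < 3) .stopf("need at least 3 distinct temperatures")
  d <- numeric(n)
  hm <- diff(temperature)[-(n - 1)]   # h_{i-1}
  hp <- diff(temperature)[-1]         # h_i
  i <- 2:(n - 1)
  d[i] <- (hm^2 * series[i + 1] - hp^2 * series[i - 1] +
           (hp^2 - hm^2) * series[i]) / (hm * hp * (hm + hp))
  d[1] <- (series[2] - series[1]) / (temperature[2] - temperature[1])
  d[n] <- (series[n] - series[n - 1]) / (temperature[n] - temperature[n - 1])
  list(temperature = temperature, derivative = d)
}

#' Restrict a thermogram or curve to a temperature window
#'
#' @param x a [thermogram()] or [rate_curve()].
#' @param t_lo,t_hi window bounds, K (`t_lo < t_hi`).
#' @return Same class as `x`, restricted to the window (boundary points
#'   retained up to floating-point tolerance).
#' @export
truncate_window <- function(x, t_lo, t_hi) UseMethod("truncate_window")

.window_keep <- function(temperature, t_lo, t_hi) {
  if (t_lo >= t_hi) .stopf("need t_lo < t_hi")
  tol <- 1e-8 * max(abs(t_lo), abs(t_hi), 1)
  keep <- temperature >= t_lo - tol & temperature <= t_hi + tol
  if (!any(keep)) .stopf("window [%.2f, %.2f] K retains no points", t_lo, t_hi)
  keep
}

#' @export
truncate_window.thermogram <- function(x, t_lo, t_hi) {
  keep <- .window_keep(x$temperature, t_lo, t_hi)
  thermogram(x$time[keep], x$temperature[keep], x$mass[keep],
             x$heat_flow[keep], x$replicate_id)
}

#' @export
truncate_window.rate_curve <- function(x, t_lo, t_hi) {
  keep <- .window_keep(x$temperature, t_lo, t_hi)
  rate_curve(x$temperature[keep], x$rate[keep], x$source)
}

#' Average replicate thermograms
#'
#' Interpolates all replicates to a common temperature grid (the
#' intersection of their ranges at 0.5 K spacing) and averages point-wise.
#' Mass channels are first normalized to a remaining-mass fraction so
#' replicates with different sample loadings (10-20 mg) are comparable,
#' then rescaled to the replicate-mean start and end masses.
#'
#' @param thermograms list of [thermogram()]s (one is returned on the
#'   common grid unchanged in shape).
#' @param by common-grid spacing, K.
#' @return A [thermogram()] with `replicate_id = "mean"`.
#' @export
average_replicates <- function(thermograms, by = 0.5) {
  if (inherits(thermograms, "thermogram")) thermograms <- list(thermograms)
  if (length(thermograms) < 1) .stopf("need at least one thermogram")
  ok <- vapply(thermograms, inherits, logical(1), "thermogram")
  if (!all(ok)) .stopf("all elements must be thermograms")
  lo <- max(vapply(thermograms, function(t) min(t$temperature), numeric(1)))
  hi <- min(vapply(thermograms, function(t) max(t$temperature), numeric(1)))
  if (lo >= hi) .stopf("replicate temperature ranges do not overlap")
  grid <- seq(lo, hi, by = by)
  interp <- function(tg, ch) stats::approx(tg$temperature, tg[[ch]],
                                           xout = grid, ties = mean)$y
  m_start <- vapply(thermograms, function(tg)
    stats::approx(tg$temperature, tg$mass, xout = lo, ties = mean)$y, numeric(1))
  m_end <- vapply(thermograms, function(tg)
    stats::approx(tg$temperature, tg$mass, xout = hi, ties = mean)$y, numeric(1))
  wbar <- rowMeans(vapply(seq_along(thermograms), function(i) {
    m <- interp(thermograms[[i]], "mass")
    (m - m_end[i]) / (m_start[i] - m_end[i])
  }, numeric(length(grid))))
  mass <- mean(m_end) + (mean(m_start) - mean(m_end)) * wbar
  time <- rowMeans(vapply(thermograms, interp, numeric(length(grid)), "time"))
  hf <- rowMeans(vapply(thermograms, interp, numeric(length(grid)), "heat_flow"))
  thermogram(time, grid, mass, hf, replicate_id = "mean")
}

#' Full preprocessing pipeline
#'
#' Smooth -> convert -> differentiate -> truncate, producing the measured
#' DTG curve, the smoothed heat-flow curve and its temperature derivative,
#' all on the analysis window.
#'
#' @param tg a [thermogram()] (average replicates first if needed).
#' @param window analysis window, K; default 200-600 C.
#' @param sg_window,sg_order Savitzky-Golay settings applied once to the
#'   mass and heat-flow channels.
#' @return List with `dtg` (measured [rate_curve()]), `dsc` (data.frame
#'   `temperature`, `heat_flow`), and `dsc_derivative` (data.frame
#'   `temperature`, `derivative`).
#' @export
preprocess_thermogram <- function(tg,
                                  window = c(celsius_to_kelvin(200),
                                             celsius_to_kelvin(600)),
                                  sg_window = 21, sg_order = 3) {
  stopifnot(inherits(tg, "thermogram"))
  sm <- tg
  sm$mass <- savitzky_golay(tg$mass, sg_window, sg_order)
  sm$mass <- pmax(sm$mass, .Machine$double.eps)
  sm$heat_flow <- savitzky_golay(tg$heat_flow, sg_window, sg_order)
  x <- conversion_from_mass(sm, window)
  dx <- derivative_wrt_temperature(x, sm$temperature)
  keep <- .window_keep(dx$temperature, window[1], window[2])
  dtg <- rate_curve(dx$temperature[keep], dx$derivative[keep], "measured")
  dhf <- derivative_wrt_temperature(sm$heat_flow, sm$temperature)
  keep_h <- .window_keep(dhf$temperature, window[1], window[2])
  keep_raw <- .window_keep(sm$temperature, window[1], window[2])
  list(dtg = dtg,
       dsc = data.frame(temperature = sm$temperature[keep_raw],
                        heat_flow = sm$heat_flow[keep_raw]),
       dsc_derivative = data.frame(temperature = dhf$temperature[keep_h],
                                   derivative = dhf$derivative[keep_h]))
}
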