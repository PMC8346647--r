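## First-order DAEM forward model.
##
## For a single activation energy E under a constant heating rate beta
## (K s^-1) starting at T0, the conversion rate of a first-order reaction is
##
##   dx/dT = (k0/beta) exp[ -( E/(R T) + (k0/beta) I(T) ) ],
##   I(T)  = integral_{T0}^{T} exp(-E/(R T')) dT'
##
## and the DAEM rate is the expectation of this over E ~ F(E). A mixture of
## N pseudo-components with fractions c_i sums the per-component rates:
## dx/dT = sum_i c_i dx/dT|_i.

#' Constant heating program
#'
#' @param beta heating rate, K s^-1 (use [c_per_min_to_k_per_s()] for the
#'   instrument convention; 5 C min^-1 = 0.08333 K s^-1).
#' @param t_start program start temperature T0, K. The inner Arrhenius
#'   integral runs from here, i.e. from the furnace start (ambient), not
#'   from the analysis window.
#' @param t_end program end temperature, K.
#' @return Object of class `heating_program`.
#' @examples
#' heating_program(c_per_min_to_k_per_s(5), celsius_to_kelvin(22), celsius_to_kelvin(600))
#' @export
heating_program <- function(beta = c_per_min_to_k_per_s(5),
                            t_start = celsius_to_kelvin(22),
                            t_end = celsius_to_kelvin(600)) {
  if (!.is_number(beta) || beta <= 0) .stopf("beta must be a positive heating rate (K s^-1)")
  if (!.is_number(t_start) || !.is_number(t_end) || t_start <= 0 || t_end <= t_start)
    .stopf("need t_end > t_start > 0 (Kelvin)")
  structure(list(beta = beta, t_start = t_start, t_end = t_end),
            class = "heating_program")
}

#' Pseudo-component of a DAEM mixture
#'
#' @param fraction contribution fraction c_i in [0, 1].
#' @param dist a [dist_spec()] for the component's activation energies.
#' @param k0 Arrhenius pre-exponential factor, s^-1. Fixed by default at
#'   1.67e13 s^-1 for every component, which pins down E against the
#'   kinetic compensation effect.
#' @return Object of class `pseudo_component`.
#' @export
pseudo_component <- function(fraction, dist, k0 = 1.67e13) {
  if (!.is_number(fraction) || fraction < 0 || fraction > 1)
    .stopf("fraction must lie in [0, 1]")
  stopifnot(inherits(dist, "dist_spec"))
  if (!.is_number(k0) || k0 <= 0) .stopf("k0 must be positive (s^-1)")
  structure(list(fraction = fraction, dist = dist, k0 = k0),
            class = "pseudo_component")
}

#' DAEM mixture model
#'
#' @param components list of [pseudo_component()]s whose fractions sum to 1
#'   (within 1e-8).
#' @param program a [heating_program()].
#' @return Object of class `daem_model`.
#' @export
daem_model <- function(components, program = heating_program()) {
  if (inherits(components, "pseudo_component")) components <- list(components)
  if (length(components) == 0) .stopf("model needs at least one pseudo-component")
  ok <- vapply(components, inherits, logical(1), "pseudo_component")
  if (!all(ok)) .stopf("components must all be pseudo_component objects")
  fr <- vapply(components, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8)
    .stopf("component fractions must sum to 1 (got %.10f)", sum(fr))
  stopifnot(inherits(program, "heating_program"))
  structure(list(components = components, program = program),
            class = "daem_model")
}

#' @export
print.daem_model <- function(x, ...) {
  cat(sprintf("<daem_model> %d pseudo-component(s), beta = %.4f C min^-1\n",
              length(x$components), x$program$beta * 60))
  for (i in seq_along(x$components)) {
    cmp <- x$components[[i]]
    cat(sprintf("  [%d] c = %.4f  %s(E = %.4f, sigma = %.4f kJ mol^-1)  k0 = %.3g s^-1\n",
                i, cmp$fraction, cmp$dist$family,
                cmp$dist$e_mean / 1000, cmp$dist$sigma / 1000, cmp$k0))
  }
  invisible(x)
}

#' Conversion-rate (DTG) curve
#'
#' A temperature grid with dx/dT values and a provenance tag.
#'
#' @param temperature strictly increasing grid, K.
#' @param rate dx/dT values, K^-1.
#' @param source `"simulated"` or `"measured"`.
#' @return Object of class `rate_curve` (also coercible with
#'   `as.data.frame`).
#' @export
rate_curve <- function(temperature, rate, source = c("simulated", "measured")) {
  source <- match.arg(source)
  if (length(temperature) != length(rate)) .stopf("temperature and rate lengths differ")
  if (any(diff(temperature) <= 0)) .stopf("temperature grid must be strictly increasing")
  if (source == "simulated" && any(rate < -1e-12))
    .stopf("simulated rates must be non-negative")
  structure(list(temperature = as.numeric(temperature),
                 rate = as.numeric(rate), source = source),
            class = "rate_curve")
}

#' @export
as.data.frame.rate_curve <- function(x, ...) {
  data.frame(temperature = x$temperature, rate = x$rate)
}

#' @export
print.rate_curve <- function(x, ...) {
  cat(sprintf("<rate_curve> %s, %d points, %.1f-%.1f C, peak %.3e K^-1\n",
              x$source, length(x$temperature),
              kelvin_to_celsius(min(x$temperature)),
              kelvin_to_celsius(max(x$temperature)), max(x$rate)))
  invisible(x)
}

#' Default simulation/analysis temperature grid
#'
#' 200-600 C at 0.5 K spacing, the analysis window within which moisture
#' removal and light-volatile evaporation no longer contribute.
#'
#' @param t_lo,t_hi window bounds, K.
#' @param by grid spacing, K.
#' @return Numeric grid, K.
#' @export
default_grid <- function(t_lo = celsius_to_kelvin(200),
                         t_hi = celsius_to_kelvin(600), by = 0.5) {
  seq(t_lo, t_hi, by = by)
}

## refined grid for the inner Arrhenius integral; step <= 0.25 K keeps the
## cumulative trapezoid error far below the quadrature tolerances
.refined_grid <- function(t0, t_max, step = 0.25) {
  n <- ceiling((t_max - t0) / step)
  seq(t0, t_max, length.out = max(n + 1, 2))
}

#' Inner Arrhenius temperature integral
#'
#' Cumulative values of `integral_{t0}^{t} exp(-e/(R T')) dT'` on a
#' temperature grid, evaluated by cumulative trapezoid on a refined grid
#' (default step 0.25 K) and interpolated to `t`.
#'
#' @param e activation energy, J mol^-1 (scalar, >= 0).
#' @param t0 lower limit, K.
#' @param t increasing temperature grid with `t[1] >= t0`, K.
#' @param step refinement step, K.
#' @return Non-decreasing integral values at `t`, K.
#' @export
temperature_integral <- function(e, t0, t, step = 0.25) {
  if (!.is_number(e) || e < 0) .stopf("activation energy must be non-negative")
  if (length(t) > 1 && any(diff(t) <= 0)) .stopf("t grid must be strictly increasing")
  if (t[1] < t0 - 1e-9) .stopf("t grid must start at or after t0")
  if (max(t) <= t0) return(numeric(length(t)))
  tref <- .refined_grid(t0, max(t), step)
  f <- exp(-e / (R_GAS * tref))
  cum <- pracma::cumtrapz(tref, f)[, 1]
  ## Euler-Maclaurin endpoint correction with the analytic derivative of
  ## the integrand lifts the uniform trapezoid from O(h^2) to O(h^4)
  h <- tref[2] - tref[1]
  fp <- f * e / (R_GAS * tref^2)
  cum <- cum - h^2 / 12 * (fp - fp[1])
  ## close each query's partial segment with an exact mini-trapezoid of the
  ## analytic integrand rather than interpolating the cumulative
  tq <- pmax(t, t0)
  idx <- pmin(findInterval(tq, tref), length(tref))
  cum[idx] + (tq - tref[idx]) * (f[idx] + exp(-e / (R_GAS * tq))) / 2
}

## Batched rate evaluation: one column per (energy, k0) pair, rows = tout.
## Shares the refined grid and the single-pass cumulative sum across all
## energies of all components in a mixture, which is what makes repeated
## residual evaluations affordable.
.rate_matrix <- function(e_nodes, k0, beta, t0, tout, step = 0.5) {
  if (length(k0) == 1) k0 <- rep(k0, length(e_nodes))
  .rate_matrix_cpp(as.numeric(e_nodes), as.numeric(k0), beta, t0,
                   as.numeric(tout), step, R_GAS)
}

#' Single-energy first-order conversion rate
#'
#' dx/dT for one activation energy under a constant heating program: the
#' sigma -> 0 limit of the DAEM.
#'
#' @param e activation energy, J mol^-1.
#' @param k0 pre-exponential factor, s^-1.
#' @param program a [heating_program()].
#' @param t increasing temperature grid, K.
#' @param step inner-integral refinement step, K (default 0.5; the corrected trapezoid is fourth-order, so this resolves the integrand to well below fitting tolerances).
#' @return Rate values, K^-1.
#' @export
single_energy_rate <- function(e, k0, program, t, step = 0.5) {
  if (!.is_number(e) || e < 0) .stopf("activation energy must be non-negative")
  stopifnot(inherits(program, "heating_program"))
  as.vector(.rate_matrix(e, k0, program$beta, program$t_start, t, step))
}

#' DAEM rate of one pseudo-component
#'
#' Quadrature of [single_energy_rate()] against the component's F(E) nodes
#' and weights. Degenerate sigma takes the exact single-energy path.
#'
#' @param comp a [pseudo_component()] (its `fraction` is not applied here).
#' @param program a [heating_program()].
#' @param t increasing temperature grid, K.
#' @param n_nodes energy quadrature nodes (default 201).
#' @param coverage support coverage for [dist_nodes()].
#' @param step inner-integral refinement step, K (default 0.5; the corrected trapezoid is fourth-order, so this resolves the integrand to well below fitting tolerances).
#' @return A simulated [rate_curve()].
#' @export
component_rate <- function(comp, program, t = default_grid(), n_nodes = 201,
                           coverage = NULL, step = 0.5) {
  stopifnot(inherits(comp, "pseudo_component"), inherits(program, "heating_program"))
  nd <- dist_nodes(comp$dist, n = n_nodes, coverage = coverage)
  rt <- as.vector(.rate_matrix(nd$e, comp$k0, program$beta, program$t_start,
                               t, step) %*% nd$w)
  rate_curve(t, pmax(rt, 0), "simulated")
}

#' DAEM rate of a pseudo-component mixture
#'
#' Weighted sum `sum_i c_i dx/dT|_i` over the model's components. All
#' components' energy nodes are evaluated in one batched pass.
#'
#' @param model a [daem_model()].
#' @param t increasing temperature grid, K.
#' @inheritParams component_rate
#' @return A simulated [rate_curve()] whose `"components"` attribute holds
#'   the list of weighted per-component curves c_i dx/dT|_i (for plotting
#'   and deconvolution displays).
#' @export
mixture_rate <- function(model, t = default_grid(), n_nodes = 201,
                         coverage = NULL, step = 0.5) {
  stopifnot(inherits(model, "daem_model"))
  nodes <- lapply(model$components, function(cmp)
    dist_nodes(cmp$dist, n = n_nodes, coverage = coverage))
  e_all <- unlist(lapply(nodes, `[[`, "e"))
  k0_all <- unlist(mapply(function(cmp, nd) rep(cmp$k0, length(nd$e)),
                          model$components, nodes, SIMPLIFY = FALSE))
  M <- .rate_matrix(e_all, k0_all, model$program$beta, model$program$t_start,
                    t, step)
  off <- 0
  comp_curves <- vector("list", length(model$components))
  total <- numeric(length(t))
  for (i in seq_along(model$components)) {
    nd <- nodes[[i]]
    cols <- off + seq_along(nd$e)
    ri <- as.vector(M[, cols, drop = FALSE] %*% nd$w)
    ri <- pmax(ri, 0) * model$components[[i]]$fraction
    comp_curves[[i]] <- rate_curve(t, ri, "simulated")
    total <- total + ri
    off <- off + length(nd$e)
  }
  structure(rate_curve(t, total, "simulated"), components = comp_curves)
}

#' Cumulative conversion from a rate curve
#'
#' Trapezoid cumulative integral of dx/dT over the grid; starts at 0 and is
#' non-decreasing for non-negative rates.
#'
#' @param curve a [rate_curve()].
#' @return Numeric x(T) on the curve's grid.
#' @export
conversion_curve <- function(curve) {
  stopifnot(inherits(curve, "rate_curve"))
  pracma::cumtrapz(curve$temperature, curve$rate)[, 1]
}

#' Peak temperature of a rate curve
#'
#' Grid argmax refined by a quadratic through the three points around the
#' maximum (exact for a locally parabolic peak).
#'
#' @param curve a [rate_curve()] with at least 5 points.
#' @return Peak temperature, K.
#' @export
peak_temperature <- function(curve) {
  stopifnot(inherits(curve, "rate_curve"))
  tt <- curve$temperature; y <- curve$rate
  if (length(tt) < 5) .stopf("need at least 5 points to locate a peak")
  if (max(y) - min(y) <= 0) .stopf("flat curve has no peak")
  i <- which.max(y)
  if (i == 1 || i == length(y)) return(tt[i])
  x0 <- tt[i]
  xm <- tt[i - 1] - x0; xp <- tt[i + 1] - x0
  ym <- y[i - 1]; y0 <- y[i]; yp <- y[i + 1]
  ## quadratic vertex through (xm,ym),(0,y0),(xp,yp)
  denom <- xm * xp * (xm - xp)
  a <- (xp * (ym - y0) - xm * (yp - y0)) / denom
  b <- (xm^2 * (yp - y0) - xp^2 * (ym - y0)) / denom
  if (a >= 0) return(x0)    # not locally concave: keep grid argmax
  x0 - b / (2 * a)
}

#' Peak temperature of a single first-order reaction
#'
#' Solves the first-order peak (Kissinger) condition
#' `E beta / (R Tp^2) = k0 exp(-E/(R Tp))` for Tp, and its inverse for E.
#'
#' @param e activation energy, J mol^-1.
#' @param k0 pre-exponential factor, s^-1.
#' @param beta heating rate, K s^-1.
#' @return Peak temperature, K (for [kissinger_peak_temperature()]) or
#'   activation energy, J mol^-1 (for [kissinger_energy()]).
#' @export
kissinger_peak_temperature <- function(e, k0 = 1.67e13,
                                       beta = c_per_min_to_k_per_s(5)) {
  f <- function(Tp) log(e * beta / (R_GAS * Tp^2)) - log(k0) + e / (R_GAS * Tp)
  stats::uniroot(f, c(200, 3000), tol = 1e-10)$root
}

#' @rdname kissinger_peak_temperature
#' @param t_peak observed peak temperature, K.
#' @export
kissinger_energy <- function(t_peak, k0 = 1.67e13,
                             beta = c_per_min_to_k_per_s(5)) {
  f <- function(e) log(e * beta / (R_GAS * t_peak^2)) - log(k0) + e / (R_GAS * t_peak)
  stats::uniroot(f, c(1e4, 1e6), tol = 1e-8)$root
}
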