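## Bounded nonlinear least-squares estimation of DAEM mixture parameters.
##
## The objective is the unweighted residual dx/dT|exp - dx/dT|sim on the
## data grid. Fractions live on the simplex by construction (N-1 logits),
## activation energies and scales are box-bounded, and the optimizer is the
## Levenberg-Marquardt trust-region solver of minpack.lm. Initialization
## reads peak positions off the data and inverts the first-order peak
## condition for starting energies.

#' Fit configuration
#'
#' @param n_components number of pseudo-components (>= 1).
#' @param family one distribution family for all components, as the method
#'   compares families one at a time.
#' @param k0 fixed pre-exponential factor, s^-1 (scalar, shared by all
#'   components, or one per component).
#' @param e_bounds bounds on each mean activation energy, J mol^-1.
#'   Defaults span the literature range for biomass components with
#'   padding.
#' @param sigma_bounds bounds on each scale, J mol^-1.
#' @param init `"peaks"` for peak-based initialization, or an explicit list
#'   with `fractions`, `e_mean` (J mol^-1) and `sigma` (J mol^-1).
#' @param seed integer seed controlling restart jitter (the base fit is
#'   deterministic regardless).
#' @param max_restarts number of jittered restarts beyond the deterministic
#'   initial fit; the best residual norm wins.
#' @param n_nodes,coverage,step forward-model quadrature settings (see
#'   [mixture_rate()]).
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(n_components = 1, family = DIST_FAMILIES,
                       k0 = 1.67e13,
                       e_bounds = c(50e3, 350e3),
                       sigma_bounds = c(1, 60e3),
                       init = "peaks", seed = 1L, max_restarts = 2,
                       n_nodes = 201, coverage = NULL, step = 0.5) {
  family <- match.arg(family)
  if (!.is_number(n_components) || n_components < 1) .stopf("n_components must be >= 1")
  if (any(k0 <= 0)) .stopf("k0 must be positive")
  if (e_bounds[1] >= e_bounds[2] || sigma_bounds[1] >= sigma_bounds[2])
    .stopf("bounds must be ordered (lower < upper)")
  structure(list(n_components = as.integer(n_components), family = family,
                 k0 = k0, e_bounds = e_bounds, sigma_bounds = sigma_bounds,
                 init = init, seed = as.integer(seed),
                 max_restarts = as.integer(max_restarts),
                 n_nodes = n_nodes, coverage = coverage, step = step),
            class = "fit_config")
}

## ---- parameter encoding: c(logits[n-1], E_kJ[n], log sigma_kJ[n]) ----
## logits keep fractions on the simplex by construction; kJ / log-kJ scale
## the search space to O(1)-O(100) for the trust region.

.softmax_fractions <- function(logits) {
  z <- c(.clipped_exp(logits), 1)
  z / sum(z)
}

.encode_params <- function(fractions, e_mean, sigma) {
  n <- length(fractions)
  logits <- if (n > 1) log(pmax(fractions[-n], 1e-12) / max(fractions[n], 1e-12)) else numeric(0)
  c(logits, e_mean / 1000, log(sigma / 1000))
}

.decode_params <- function(p, n) {
  fractions <- if (n > 1) .softmax_fractions(p[seq_len(n - 1)]) else 1
  list(fractions = fractions,
       e_mean = p[n:(2 * n - 1)] * 1000,
       sigma = exp(p[(2 * n):(3 * n - 1)]) * 1000)
}

.param_bounds <- function(config) {
  n <- config$n_components
  list(lower = c(rep(-20, n - 1), rep(config$e_bounds[1] / 1000, n),
                 rep(log(config$sigma_bounds[1] / 1000), n)),
       upper = c(rep(20, n - 1), rep(config$e_bounds[2] / 1000, n),
                 rep(log(config$sigma_bounds[2] / 1000), n)))
}

.build_model <- function(pars, config, program) {
  n <- config$n_components
  k0 <- if (length(config$k0) == 1) rep(config$k0, n) else config$k0
  comps <- lapply(seq_len(n), function(i)
    pseudo_component(pars$fractions[i],
                     dist_spec(config$family, pars$e_mean[i],
                               max(pars$sigma[i], 0)),
                     k0[i]))
  ## renormalize defensively against logit round-off
  fr <- vapply(comps, `[[`, numeric(1), "fraction")
  for (i in seq_len(n)) comps[[i]]$fraction <- fr[i] / sum(fr)
  daem_model(comps, program)
}

#' Residual vector of a DAEM model against a measured DTG curve
#'
#' Element-wise experimental-minus-simulated dx/dT on the data grid,
#' unweighted.
#'
#' @param model a [daem_model()] (or a list with `fractions`, `e_mean`,
#'   `sigma` to be combined with `config`).
#' @param data a [rate_curve()].
#' @param config a [fit_config()] supplying quadrature settings (and the
#'   family/k0 when `model` is a bare parameter list).
#' @return Residuals on the data grid.
#' @export
residual_vector <- function(model, data, config = fit_config()) {
  if (inherits(data, "rate_curve")) data <- list(data)
  stopifnot(all(vapply(data, inherits, logical(1), "rate_curve")))
  if (!inherits(model, "daem_model"))
    model <- .build_model(model, config, heating_program())
  unlist(lapply(data, function(d) {
    sim <- mixture_rate(model, d$temperature, n_nodes = config$n_nodes,
                        coverage = config$coverage, step = config$step)
    if (any(!is.finite(sim$rate)))
      .stopf("non-finite simulated rates at parameters: %s",
             paste(sprintf("E=%.1f",
                           vapply(model$components, function(c) c$dist$e_mean, 1)),
                   collapse = ", "))
    d$rate - sim$rate
  }), use.names = FALSE)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with SS_tot about the observed mean.
#'
#' @param observed,fitted [rate_curve()]s on a common grid, or numeric
#'   vectors of equal length.
#' @return R-squared (<= 1).
#' @export
r_squared <- function(observed, fitted) {
  obs <- if (inherits(observed, "rate_curve")) observed$rate else observed
  fit <- if (inherits(fitted, "rate_curve")) fitted$rate else fitted
  if (inherits(observed, "rate_curve") && inherits(fitted, "rate_curve") &&
      (length(observed$temperature) != length(fitted$temperature) ||
       any(abs(observed$temperature - fitted$temperature) > 1e-6)))
    .stopf("curves are not on a common grid")
  if (length(obs) != length(fit)) .stopf("lengths differ")
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) .stopf("zero-variance observations: R^2 undefined")
  1 - sum((obs - fit)^2) / ss_tot
}

## ---- peak-based initialization -------------------------------------------

## strict local maxima (interior sign changes of the first difference)
.local_maxima <- function(y) which(diff(sign(diff(y))) == -2) + 1L

## topographic prominence of peak index i: height above the higher of the
## two valley floors separating it from higher terrain
.peak_prominence <- function(y, idx) {
  vapply(idx, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1)]
    right <- y[seq(i + 1, length(y))]
    lb <- if (any(left >= h)) min(left[max(which(left >= h)):(i - 1)]) else min(left)
    rb <- if (any(right >= h)) min(right[1:min(which(right >= h))]) else min(right)
    h - max(lb, rb)
  }, numeric(1))
}

## shoulder candidates: local minima of the smoothed second derivative
## (negative curvature marks a buried peak even without a local maximum)
.curvature_candidates <- function(tt, y, frac = 0.02) {
  n <- length(y)
  if (n < 9) return(integer(0))
  w <- min(21, if (n %% 2 == 1) n else n - 1)
  if (w %% 2 == 0) w <- w - 1
  if (w <= 3) return(integer(0))
  d1 <- derivative_wrt_temperature(y, tt)$derivative
  d2 <- derivative_wrt_temperature(d1, tt)$derivative
  d2s <- savitzky_golay(d2, window = w, order = 2)
  cand <- which(diff(sign(diff(d2s))) == 2) + 1L   # local minima of d2
  cand[d2s[cand] < -frac * max(abs(d2s))]
}

#' Peak-based initial parameters for a DAEM fit
#'
#' Detects up to `n` candidate reaction peaks in a DTG curve - prominent
#' local maxima first, then negative-curvature shoulders (overlapping
#' components often appear only as shoulders) - inverts the first-order
#' peak condition for starting activation energies, estimates starting
#' scales from peak widths, and apportions starting fractions by nearest-
#' peak area. Missing candidates are padded at high-temperature area
#' quantiles. A flat curve falls back to area-quantile-spaced temperatures
#' (flagged via the `fallback` attribute).
#'
#' @param data a measured or simulated [rate_curve()].
#' @param n number of components to initialize.
#' @param family distribution family tag (stored, not used numerically).
#' @param k0 pre-exponential factor, s^-1.
#' @param program a [heating_program()] (supplies beta).
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   curve maximum.
#' @return List with `fractions`, `e_mean` (J mol^-1), `sigma` (J mol^-1)
#'   and `t_peaks` (K), ordered by temperature; attribute `fallback` is
#'   TRUE when no peak was detectable.
#' @export
initialize_from_peaks <- function(data, n, family = "gaussian", k0 = 1.67e13,
                                  program = heating_program(),
                                  prominence_frac = 0.02) {
  stopifnot(inherits(data, "rate_curve"))
  tt <- data$temperature; y <- data$rate
  fallback <- FALSE
  area <- pracma::cumtrapz(tt, pmax(y, 0))[, 1]
  total <- area[length(area)]

  if (max(y) - min(y) <= 0 || total <= 0) {
    ## flat / non-informative: spread over even area (or temperature) quantiles
    fallback <- TRUE
    probs <- (seq_len(n) - 0.5) / n
    t_peaks <- if (total > 0) stats::approx(area / total, tt, xout = probs, ties = "ordered")$y
               else stats::quantile(tt, probs, names = FALSE)
  } else {
    imax <- .local_maxima(y)
    imax <- imax[.peak_prominence(y, imax) >= prominence_frac * max(y)]
    imax <- imax[order(.peak_prominence(y, imax), decreasing = TRUE)]
    chosen <- utils::head(imax, n)
    if (length(chosen) < n) {
      sh <- .curvature_candidates(tt, y)
      sh <- sh[!vapply(sh, function(i) any(abs(tt[i] - tt[chosen]) < 10), logical(1))]
      if (length(sh) > 1) {
        d1 <- derivative_wrt_temperature(y, tt)$derivative
        d2 <- derivative_wrt_temperature(d1, tt)$derivative
        sh <- sh[order(d2[sh])]   # most negative curvature first
      }
      chosen <- c(chosen, utils::head(sh, n - length(chosen)))
    }
    t_peaks <- sort(tt[chosen])
    deficit <- n - length(t_peaks)
    if (deficit > 0) {
      ## pad on the high-temperature shoulder by area quantiles above the
      ## hottest detected peak
      a_hi <- stats::approx(tt, area, xout = max(t_peaks, tt[1]))$y
      probs <- a_hi + (seq_len(deficit) / (deficit + 1)) * (total - a_hi)
      pads <- stats::approx(area, tt, xout = probs, ties = "ordered")$y
      pads[!is.finite(pads)] <- max(tt) - (max(tt) - max(t_peaks)) / 2
      t_peaks <- sort(c(t_peaks, pads))
    }
  }

  e0 <- vapply(t_peaks, kissinger_energy, numeric(1),
               k0 = k0[1], beta = program$beta)

  ## starting scale from observed peak width: a single-energy first-order
  ## peak has FWHM ~ 2.446 R Tp^2 / E in temperature; width beyond that is
  ## attributed to the energy distribution via dTp/dE
  sigma0 <- vapply(seq_along(t_peaks), function(j) {
    tp <- t_peaks[j]
    i0 <- which.min(abs(tt - tp))
    h <- y[i0]
    if (h <= 0) return(3000)
    lo_lim <- if (j > 1) (t_peaks[j - 1] + tp) / 2 else tt[1]
    hi_lim <- if (j < length(t_peaks)) (tp + t_peaks[j + 1]) / 2 else tt[length(tt)]
    il <- i0; while (il > 1 && tt[il] > lo_lim && y[il] > h / 2) il <- il - 1
    ir <- i0; while (ir < length(tt) && tt[ir] < hi_lim && y[ir] > h / 2) ir <- ir + 1
    fwhm <- tt[ir] - tt[il]
    fwhm0 <- 2.446 * R_GAS * tp^2 / e0[j]
    dtp_de <- (kissinger_peak_temperature(e0[j] * 1.01, k0[1], program$beta) -
               kissinger_peak_temperature(e0[j] * 0.99, k0[1], program$beta)) /
              (0.02 * e0[j])
    max(min((fwhm - fwhm0) / 2.355 / dtp_de, 20000), 1000)
  }, numeric(1))

  fractions <- if (total > 0 && !fallback) {
    nearest <- apply(abs(outer(tt, t_peaks, "-")), 1, which.min)
    a <- vapply(seq_along(t_peaks), function(j) sum(pmax(y[nearest == j], 0)), 1)
    if (sum(a) > 0) a / sum(a) else rep(1 / n, n)
  } else rep(1 / n, n)

  structure(list(fractions = fractions, e_mean = e0, sigma = sigma0,
                 t_peaks = t_peaks),
            fallback = fallback)
}

## run RNG-consuming code under a local, restorable seed
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## tight tolerances: the objective is smooth (analytic kernel), and loose
## ftol/ptol stops Levenberg-Marquardt prematurely on flat multi-component
## valleys
.lm_control <- minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-15,
                                          ptol = 1e-15, gtol = 0)

.run_lm <- function(p0, fn, bounds) {
  fit <- minpack.lm::nls.lm(p0, fn = fn, lower = bounds$lower,
                            upper = bounds$upper, control = .lm_control)
  iters <- fit$niter
  ## polish: restart LM from the solution until the deviance stalls;
  ## the trust region reinflates, which escapes premature termination
  for (k in 1:4) {
    f2 <- minpack.lm::nls.lm(fit$par, fn = fn, lower = bounds$lower,
                             upper = bounds$upper, control = .lm_control)
    iters <- iters + f2$niter
    better <- f2$deviance < fit$deviance * (1 - 1e-10)
    if (f2$deviance <= fit$deviance) fit <- f2
    if (!better) break
  }
  fit$total_iter <- iters
  fit
}

#' Fit a DAEM mixture to a DTG curve
#'
#' Bounded Levenberg-Marquardt least squares of the DAEM mixture rate
#' against a measured dx/dT curve. Fractions are optimized as N-1 logits
#' (simplex by construction), energies and scales inside box bounds. One
#' deterministic fit from the configured initialization is followed by
#' `max_restarts` jittered restarts (multiplicative log-normal, factor
#' sd 0.05, on energies and scales; Dirichlet on fractions); the smallest
#' residual norm wins. The whole procedure is deterministic given
#' `(data, config, seed)`.
#'
#' @param data a [rate_curve()] to fit, or a list of them (replicate
#'   curves): a list is fit jointly by concatenating the residual vectors,
#'   so both experiments enter the objective.
#' @param config a [fit_config()].
#' @param program a [heating_program()]; its heating rate must match the
#'   measurement.
#' @return Object of class `fit_result`: `model` (fitted [daem_model()]),
#'   `r_squared`, `residual_norm`, `n_evaluations` (optimizer iterations),
#'   `converged`, `per_component_curves`, `init_used`, `deviance`.
#' @export
fit_daem <- function(data, config = fit_config(), program = heating_program()) {
  if (inherits(data, "rate_curve")) data <- list(data)
  stopifnot(all(vapply(data, inherits, logical(1), "rate_curve")),
            inherits(config, "fit_config"))
  first <- data[[1]]
  n <- config$n_components
  init <- config$init
  if (identical(init, "peaks"))
    init <- initialize_from_peaks(first, n, config$family, config$k0[1], program)
  if (!is.list(init) || is.null(init$fractions) || is.null(init$e_mean) ||
      is.null(init$sigma))
    .stopf("init must be \"peaks\" or a list with fractions, e_mean, sigma")
  init$fractions <- init$fractions / sum(init$fractions)
  init$e_mean <- pmin(pmax(init$e_mean, config$e_bounds[1]), config$e_bounds[2])
  init$sigma <- pmin(pmax(init$sigma, config$sigma_bounds[1]), config$sigma_bounds[2])

  bounds <- .param_bounds(config)
  fn <- function(p) {
    pars <- .decode_params(p, n)
    model <- .build_model(pars, config, program)
    residual_vector(model, data, config)
  }

  starts <- list(.encode_params(init$fractions, init$e_mean, init$sigma))
  if (config$max_restarts > 0) {
    jitters <- .with_seed(config$seed, lapply(seq_len(config$max_restarts), function(r) {
      fr <- stats::rgamma(n, shape = 40 * init$fractions + 0.5)
      list(fractions = fr / sum(fr),
           e_mean = init$e_mean * exp(stats::rnorm(n, 0, 0.05)),
           sigma = init$sigma * exp(stats::rnorm(n, 0, 0.05)))
    }))
    for (j in jitters) {
      j$e_mean <- pmin(pmax(j$e_mean, config$e_bounds[1]), config$e_bounds[2])
      j$sigma <- pmin(pmax(j$sigma, config$sigma_bounds[1]), config$sigma_bounds[2])
      starts <- c(starts, list(.encode_params(j$fractions, j$e_mean, j$sigma)))
    }
  }

  best <- NULL
  iters <- 0
  any_ok <- FALSE
  for (p0 in starts) {
    fit <- tryCatch(.run_lm(p0, fn, bounds), error = function(e) NULL)
    if (is.null(fit)) next
    iters <- iters + fit$total_iter
    if (fit$info %in% 1:3) any_ok <- TRUE
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  obs_all <- unlist(lapply(data, `[[`, "rate"), use.names = FALSE)
  finish <- function(model, deviance, iters, converged) {
    sim <- mixture_rate(model, first$temperature, n_nodes = config$n_nodes,
                        coverage = config$coverage, step = config$step)
    structure(list(model = model,
                   r_squared = 1 - deviance / sum((obs_all - mean(obs_all))^2),
                   residual_norm = sqrt(deviance),
                   deviance = deviance,
                   n_evaluations = as.integer(iters),
                   converged = converged,
                   per_component_curves = attr(sim, "components"),
                   init_used = init),
              class = "fit_result")
  }

  if (is.null(best)) {
    ## no start even evaluated: report non-convergence, not an exception
    model0 <- .build_model(init, config, program)
    dev0 <- sum(residual_vector(model0, data, config)^2)
    return(finish(model0, dev0, 0L, FALSE))
  }
  finish(.build_model(.decode_params(best$par, n), config, program),
         best$deviance, iters, any_ok)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> R^2 = %.4f, residual norm = %.3e, %s\n",
              x$r_squared, x$residual_norm,
              if (x$converged) "converged" else "NOT converged"))
  print(x$model)
  invisible(x)
}

#' Tidy parameter table of a fit
#'
#' @param fit a `fit_result`.
#' @return data.frame with columns `family`, `component`, `fraction`,
#'   `e_mean_kJ_mol`, `sigma_kJ_mol`, `r_squared` (report-table layout).
#' @export
fit_parameters <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  comps <- fit$model$components
  data.frame(
    family = vapply(comps, function(c) c$dist$family, character(1)),
    component = seq_along(comps),
    fraction = vapply(comps, `[[`, numeric(1), "fraction"),
    e_mean_kJ_mol = vapply(comps, function(c) c$dist$e_mean, numeric(1)) / 1000,
    sigma_kJ_mol = vapply(comps, function(c) c$dist$sigma, numeric(1)) / 1000,
    r_squared = fit$r_squared)
}

#' Scan component counts and distribution families
#'
#' One fit per (n, family) combination; failures are recorded and the scan
#' continues.
#'
#' @param data a [rate_curve()] or list of replicate curves (see
#'   [fit_daem()]).
#' @param n_range integer vector of component counts.
#' @param families character vector of families.
#' @param config base [fit_config()] (its `n_components`/`family` are
#'   overridden per cell).
#' @param program a [heating_program()].
#' @return Object of class `model_scan`: `summary` (data.frame ordered by
#'   decreasing R-squared) and `fits` (named list of `fit_result`s, key
#'   `"<family>/n=<n>"`).
#' @seealso [scan_select()] for the parsimony tie rule.
#' @export
model_scan <- function(data, n_range, families = "gaussian",
                       config = fit_config(), program = heating_program()) {
  rows <- list(); fits <- list()
  for (fam in families) for (n in n_range) {
    cfg <- config
    cfg$n_components <- as.integer(n)
    cfg$family <- fam
    key <- sprintf("%s/n=%d", fam, n)
    fit <- tryCatch(fit_daem(data, cfg, program), error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[key]] <- data.frame(family = fam, n_components = n,
                                r_squared = NA_real_, deviance = NA_real_,
                                converged = FALSE, error = conditionMessage(fit))
    } else {
      fits[[key]] <- fit
      rows[[key]] <- data.frame(family = fam, n_components = n,
                                r_squared = fit$r_squared,
                                deviance = fit$deviance,
                                converged = fit$converged, error = NA_character_)
    }
  }
  summary <- do.call(rbind, rows)
  summary <- summary[order(-summary$r_squared), ]
  rownames(summary) <- NULL
  structure(list(summary = summary, fits = fits), class = "model_scan")
}

#' @export
print.model_scan <- function(x, ...) {
  cat("<model_scan>\n")
  print(x$summary, digits = 6)
  invisible(x)
}

#' Select the preferred fit from a scan
#'
#' Highest R-squared wins; fits within `tie_tol` of the best are ties,
#' broken toward fewer components (parsimony).
#'
#' @param scan a [model_scan()] result.
#' @param tie_tol R-squared difference below which two fits are tied.
#' @return The selected `fit_result`, with attributes `key`, `family` and
#'   `n_components`.
#' @export
scan_select <- function(scan, tie_tol = 1e-4) {
  stopifnot(inherits(scan, "model_scan"))
  s <- scan$summary[!is.na(scan$summary$r_squared), ]
  if (nrow(s) == 0) .stopf("no successful fits in scan")
  best_r2 <- max(s$r_squared)
  tied <- s[s$r_squared >= best_r2 - tie_tol, ]
  pick <- tied[order(tied$n_components, -tied$r_squared), ][1, ]
  key <- sprintf("%s/n=%d", pick$family, pick$n_components)
  structure(scan$fits[[key]], key = key, family = pick$family,
            n_components = pick$n_components)
}
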