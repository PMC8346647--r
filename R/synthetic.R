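## Synthetic TGA/DSC thermogram generator.
##
## Emulates the statistical structure the analysis assumes: a mass channel
## driven by DAEM kinetics, a heat-flow channel built from per-component
## enthalpy signs (exothermic positive), a slow linear baseline drift, and
## additive Gaussian instrument noise. DSC magnitudes are arbitrary units -
## the calorimetric channel is used qualitatively (signs and event
## positions), never calibrated.

#' Instrument-noise specification
#'
#' @param mass_noise_sd additive mass noise, as a fraction of the initial
#'   mass (default 0.1 percent).
#' @param heatflow_noise_sd additive heat-flow noise, mW.
#' @param baseline_drift linear DSC baseline wander, mW per 100 K.
#' @param seed integer seed; generation is deterministic given it.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(mass_noise_sd = 0.001, heatflow_noise_sd = 0.05,
                       baseline_drift = 0.5, seed = 1L) {
  if (mass_noise_sd < 0 || heatflow_noise_sd < 0)
    .stopf("noise standard deviations must be non-negative")
  structure(list(mass_noise_sd = mass_noise_sd,
                 heatflow_noise_sd = heatflow_noise_sd,
                 baseline_drift = baseline_drift, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Per-component enthalpy profile
#'
#' One sign and magnitude per pseudo-component: endothermic components pull
#' the simulated heat flow negative, exothermic push it positive
#' (exothermic-positive convention throughout).
#'
#' @param sign character vector, `"endo"` or `"exo"`, one per component.
#' @param magnitude peak heat-flow excursion scale per component,
#'   mW s (arbitrary calorimetric units).
#' @return Object of class `enthalpy_profile`.
#' @export
enthalpy_profile <- function(sign, magnitude) {
  if (!all(sign %in% c("endo", "exo"))) .stopf("signs must be 'endo' or 'exo'")
  if (length(sign) != length(magnitude)) .stopf("one magnitude per sign needed")
  if (any(magnitude < 0)) .stopf("magnitudes must be non-negative")
  structure(list(sign = sign, magnitude = magnitude),
            class = "enthalpy_profile")
}

#' Simulate a TGA/DSC thermogram from a DAEM model
#'
#' Mass channel: `m0 - (m0 - m_inf) x(T)` plus seeded noise. Heat-flow
#' channel: the signed, scaled sum of per-component conversion rates
#' (converted to per-second via the heating rate), plus linear drift and
#' seeded noise.
#'
#' @param model a [daem_model()].
#' @param m0 initial sample mass, mg.
#' @param m_inf residual (char) mass at burnout, mg; `m0 > m_inf > 0`.
#' @param enthalpy an [enthalpy_profile()] with one entry per component.
#' @param noise a [noise_spec()].
#' @param grid temperature grid, K; defaults to the model's full heating
#'   program at 0.5 K.
#' @param replicate_id label stored in the thermogram.
#' @param n_nodes energy quadrature nodes for the forward model.
#' @return A [thermogram()].
#' @export
simulate_thermogram <- function(model, m0 = 15, m_inf = 0.15 * m0,
                                enthalpy = NULL, noise = noise_spec(),
                                grid = NULL, replicate_id = "r1",
                                n_nodes = 201) {
  stopifnot(inherits(model, "daem_model"))
  if (!.is_number(m0) || !.is_number(m_inf) || !(m0 > m_inf && m_inf > 0))
    .stopf("need m0 > m_inf > 0 (mg)")
  if (is.null(enthalpy))
    enthalpy <- enthalpy_profile(rep("endo", length(model$components)),
                                 rep(1, length(model$components)))
  stopifnot(inherits(enthalpy, "enthalpy_profile"), inherits(noise, "noise_spec"))
  if (length(enthalpy$sign) != length(model$components))
    .stopf("enthalpy profile needs one entry per model component")
  if (is.null(grid))
    grid <- seq(model$program$t_start, model$program$t_end, by = 0.5)

  mix <- mixture_rate(model, grid, n_nodes = n_nodes)
  x <- conversion_curve(mix)
  comp <- attr(mix, "components")   # weighted curves c_i dx/dT|_i
  sgn <- ifelse(enthalpy$sign == "exo", 1, -1)
  hf_clean <- Reduce(`+`, lapply(seq_along(comp), function(i)
    sgn[i] * enthalpy$magnitude[i] * comp[[i]]$rate * model$program$beta))
  drift <- noise$baseline_drift * (grid - grid[1]) / 100

  chans <- .with_seed(noise$seed, {
    mass <- m0 - (m0 - m_inf) * x +
      stats::rnorm(length(grid), 0, noise$mass_noise_sd * m0)
    hf <- hf_clean + drift +
      stats::rnorm(length(grid), 0, noise$heatflow_noise_sd)
    list(mass = mass, hf = hf)
  })
  thermogram(time = (grid - model$program$t_start) / model$program$beta,
             temperature = grid,
             mass = pmax(chans$mass, .Machine$double.eps),
             heat_flow = chans$hf, replicate_id = replicate_id)
}

## printed kinetic parameter tables (kJ mol^-1), one column per family ----

.CELLULOSE_TABLE <- list(
  gaussian = list(e = 178.6488, s = 1.6320),
  logistic = list(e = 182.2636, s = 2.7686),
  gumbel   = list(e = 177.8279, s = 1.6634),
  cauchy   = list(e = 178.2789, s = 0.0052))

.LIGNIN_TABLE <- list(
  gaussian = list(c = c(0.4070, 0.4312, 0.0599, 0.1019),
                  e = c(174.6626, 211.1543, 157.4708, 192.7969),
                  s = c(4.6001, 22.6944, 0.0126, 2.6252)),
  logistic = list(c = c(0.1967, 0.4999, 0.0211, 0.2823),
                  e = c(174.3412, 265.3994, 157.6159, 194.1333),
                  s = c(1.3342, 50.6039, 0.0392, 6.8136)),
  gumbel   = list(c = c(0.4832, 0.3696, 0.0705, 0.0767),
                  e = c(173.5402, 209.1221, 157.5433, 193.2413),
                  s = c(4.8764, 17.0193, 0.6483, 0.0002)),
  cauchy   = list(c = c(0.5021, 0.2235, 0.0396, 0.2348),
                  e = c(174.6224, 216.9202, 157.6159, 193.4639),
                  s = c(3.5543, 8.6365, 0.0023, 4.9539)))

## scale each component's DSC magnitude so its peak excursion is
## `target` mW; keeps the qualitative channel legible at any fraction
.normalized_magnitudes <- function(model, target) {
  mix <- mixture_rate(model, n_nodes = 101)
  comp <- attr(mix, "components")
  vapply(seq_along(comp), function(i) {
    pk <- max(comp[[i]]$rate) * model$program$beta
    if (pk <= 0) 0 else target[i] / pk
  }, numeric(1))
}

#' Cellulose reference model (synthetic stand-in for the measured sample)
#'
#' Single pseudo-component at the published cellulose kinetics for the
#' requested family, with an endothermic enthalpy sign: slow-pyrolysis
#' cellulose devolatilization shows one dominant endothermic DTG/DSC event
#' near 330 C.
#'
#' @param family distribution family.
#' @return List with `model` ([daem_model()]), `enthalpy`
#'   ([enthalpy_profile()]), and suggested `m0`/`m_inf` masses, mg.
#' @export
cellulose_fixture <- function(family = "gaussian") {
  par <- .CELLULOSE_TABLE[[match.arg(family, DIST_FAMILIES)]]
  model <- daem_model(list(
    pseudo_component(1, dist_spec(family, par$e * 1000, par$s * 1000))))
  prof <- enthalpy_profile("endo", .normalized_magnitudes(model, 5))
  list(model = model, enthalpy = prof, m0 = 15, m_inf = 0.13 * 15)
}

#' Lignin reference model (synthetic stand-in for the measured sample)
#'
#' Four pseudo-components at the published lignin kinetics for the
#' requested family. Enthalpy signs follow the thermodynamic-property
#' assignments: components 1 (310 C) and 4 (372 C) endothermic-leaning,
#' components 2 (char region, 425 C) and 3 (260 C) exothermic; the
#' endo-leaning components get smaller magnitudes, mirroring the "lesser"
#' fluctuations riding on a persistent exotherm.
#'
#' @param family distribution family.
#' @return As [cellulose_fixture()].
#' @export
lignin_fixture <- function(family = "gaussian") {
  family <- match.arg(family, DIST_FAMILIES)
  par <- .LIGNIN_TABLE[[family]]
  comps <- lapply(1:4, function(i)
    pseudo_component(par$c[i], dist_spec(family, par$e[i] * 1000, par$s[i] * 1000)))
  model <- daem_model(comps)
  prof <- enthalpy_profile(c("endo", "exo", "exo", "endo"),
                           .normalized_magnitudes(model, c(2, 5, 3, 2)))
  list(model = model, enthalpy = prof, m0 = 15, m_inf = 0.40 * 15)
}

#' Simulate replicate thermograms from a fixture
#'
#' Two (or more) noisy realizations with consecutive seeds, mirroring a
#' duplicated experiment.
#'
#' @param fixture result of [cellulose_fixture()] or [lignin_fixture()].
#' @param noise base [noise_spec()]; replicate r uses `seed + r - 1`.
#' @param n_replicates number of replicates.
#' @return List of [thermogram()]s.
#' @export
fixture_replicates <- function(fixture, noise = noise_spec(),
                               n_replicates = 2) {
  lapply(seq_len(n_replicates), function(r) {
    nr <- noise; nr$seed <- noise$seed + r - 1L
    simulate_thermogram(fixture$model, m0 = fixture$m0, m_inf = fixture$m_inf,
                        enthalpy = fixture$enthalpy, noise = nr,
                        replicate_id = sprintf("r%d", r))
  })
}

#' Materialize synthetic fixture files
#'
#' Writes two-replicate cellulose and lignin thermogram CSVs into a
#' directory (filenames carry the `synthetic_` prefix).
#'
#' @param dir output directory (created if missing).
#' @param seed base noise seed.
#' @return Invisibly, the written paths.
#' @export
write_fixture_files <- function(dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (sample in c("cellulose", "lignin")) {
    fx <- if (sample == "cellulose") cellulose_fixture() else lignin_fixture()
    reps <- fixture_replicates(fx, noise_spec(seed = seed))
    for (i in seq_along(reps)) {
      p <- file.path(dir, sprintf("synthetic_%s_r%d.csv", sample, i))
      write_thermogram(reps[[i]], p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
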