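program5 <- heating_program()   # 5 C/min, 22 -> 600 C

test_that("temperature integral: limits, oracle, monotonicity", {
  t <- seq(300, 900, by = 10)
  # e = 0 makes the integrand 1
  expect_equal(temperature_integral(0, 300, t), t - 300, tolerance = 1e-10)
  expect_equal(temperature_integral(1.5e5, 300, 300), 0)

  e <- 178648.8
  got <- temperature_integral(e, 295.15, seq(400, 603.15, by = 50))
  oracle <- vapply(seq(400, 603.15, by = 50), function(tt)
    stats::integrate(function(u) exp(-e / (R_GAS * u)), 295.15, tt,
                     rel.tol = 1e-12)$value, numeric(1))
  expect_lt(max(abs(got - oracle) / pmax(oracle, 1e-300)), 1e-6)
  expect_true(all(diff(temperature_integral(e, 295.15, seq(300, 900, 1))) >= 0))
  expect_error(temperature_integral(-1, 300, t), "non-negative")
})

test_that("single-energy rate peaks at the Kissinger temperature and conserves mass", {
  e <- 178648.8; k0 <- 1.67e13
  t <- seq(350, 1000, by = 0.5)   # wide grid for full burnout
  r <- single_energy_rate(e, k0, program5, t)
  tp_grid <- t[which.max(r)]
  tp_kiss <- kissinger_peak_temperature(e, k0, program5$beta)
  expect_lt(abs(tp_grid - tp_kiss), 0.5)

  # complete conversion of a first-order reaction
  expect_close(pracma::trapz(t, r), 1, 1e-3)

  # at the program start the survival factor is ~1
  t0 <- program5$t_start
  r0 <- single_energy_rate(e, k0, program5, c(t0, t0 + 1))
  expect_close(r0[1], (k0 / program5$beta) * exp(-e / (R_GAS * t0)),
               1e-6 * (k0 / program5$beta) * exp(-e / (R_GAS * t0)))
})

test_that("peak refinement recovers the Kissinger root to sub-grid accuracy", {
  e <- 178648.8
  t <- seq(450, 750, by = 0.5)
  curve <- rate_curve(t, single_energy_rate(e, 1.67e13, program5, t))
  expect_lt(abs(peak_temperature(curve) -
                kissinger_peak_temperature(e, 1.67e13, program5$beta)), 0.5)

  # symmetric triangle centered at 600 K
  tri <- rate_curve(seq(590, 610, 1), pmax(0, 10 - abs(seq(590, 610, 1) - 600)) / 100)
  expect_equal(peak_temperature(tri), 600)
  flat <- rate_curve(seq(500, 600, 1), rep(0, 101))
  expect_error(peak_temperature(flat), "flat")
})

test_that("degenerate sigma reduces the DAEM to the single-energy rate", {
  t <- default_grid()
  comp <- pseudo_component(1, dist_spec("gaussian", 178648.8, 0.5))
  daem <- component_rate(comp, program5, t)
  single <- single_energy_rate(178648.8, 1.67e13, program5, t)
  expect_lt(max(abs(daem$rate - single)), 1e-10)
})

test_that("component peak temperatures match the reported maximum mass-loss points", {
  # cellulose: single gaussian stage peaks near 330 C
  cell <- component_rate(pseudo_component(1, dist_spec("gaussian", 178648.8, 1632)),
                         program5)
  expect_close(kelvin_to_celsius(peak_temperature(cell)), 330, 5)

  # lignin stage 3 (near-degenerate gaussian) peaks near 260 C
  lig3 <- component_rate(pseudo_component(1, dist_spec("gaussian", 157470.8, 12.6)),
                         program5)
  expect_close(kelvin_to_celsius(peak_temperature(lig3)), 260, 5)
})

test_that("component quadrature agrees with a brute-force dense oracle", {
  # dense-grid oracle: 4001 energy nodes, 0.05 K inner integral
  dense_rate <- function(spec, k0, t) {
    nd <- dist_nodes(spec, n = 4001)
    r <- numeric(length(t))
    for (j in seq_along(nd$e)) {
      I <- temperature_integral(nd$e[j], program5$t_start, t, step = 0.05)
      r <- r + nd$w[j] * (k0 / program5$beta) *
        exp(pmin(-(nd$e[j] / (R_GAS * t) + (k0 / program5$beta) * I), 700))
    }
    r
  }
  t <- seq(celsius_to_kelvin(200), celsius_to_kelvin(600), by = 5)
  for (par in list(c(178648.8, 1632), c(211154.3, 22694.4))) {
    spec <- dist_spec("gaussian", par[1], par[2])
    got <- component_rate(pseudo_component(1, spec), program5, t)$rate
    want <- dense_rate(spec, 1.67e13, t)
    expect_lt(max(abs(got - want)) / max(want), 1e-4)
  }
})

test_that("mixture rate is the fraction-weighted sum with per-component curves", {
  t <- default_grid()
  spec <- dist_spec("gaussian", 178648.8, 1632)
  single <- component_rate(pseudo_component(1, spec), program5, t)

  m1 <- daem_model(list(pseudo_component(1, spec)), program5)
  expect_equal(mixture_rate(m1, t)$rate, single$rate, tolerance = 1e-12)

  # two identical components at c = (0.3, 0.7) collapse to the single curve
  m2 <- daem_model(list(pseudo_component(0.3, spec), pseudo_component(0.7, spec)),
                   program5)
  mx <- mixture_rate(m2, t)
  expect_lt(max(abs(mx$rate - single$rate)), 1e-10)
  comps <- attr(mx, "components")
  expect_length(comps, 2)
  expect_close(max(comps[[1]]$rate) / max(single$rate), 0.3, 1e-9)

  expect_error(daem_model(list(pseudo_component(0.3, spec),
                               pseudo_component(0.3, spec))), "sum to 1")
})

test_that("four-component lignin mixture shows the reported peak structure", {
  mix <- lignin_curve()
  # dominant peak near 310 C
  expect_close(kelvin_to_celsius(peak_temperature(mix)), 310, 8)
  # resolvable structure at the high-temperature stage
  pk <- find_dtg_peaks(mix, prominence_frac = 0.02, smooth_span_K = 0)
  expect_true(any(abs(kelvin_to_celsius(pk$temperature) - 372) < 8))
})

test_that("conversion curve properties", {
  t <- default_grid()
  zero <- rate_curve(t, rep(0, length(t)))
  expect_true(all(conversion_curve(zero) == 0))

  wide <- seq(350, 1000, by = 0.5)
  r <- rate_curve(wide, single_energy_rate(178648.8, 1.67e13, program5, wide))
  x <- conversion_curve(r)
  expect_true(all(diff(x) >= 0))
  expect_close(x[length(x)], 1, 1e-3)
  # conversion at the rate maximum: near the classic 1 - 1/e, and equal to
  # 1 - exp(-(k0/beta) I(Tp)) from an independent adaptive quadrature
  tp <- peak_temperature(r)
  xp <- stats::approx(wide, x, xout = tp)$y
  expect_close(xp, 1 - exp(-1), 0.03)
  I_p <- stats::integrate(function(u) exp(-178648.8 / (R_GAS * u)),
                          program5$t_start, tp, rel.tol = 1e-12)$value
  expect_close(xp, 1 - exp(-(1.67e13 / program5$beta) * I_p), 1e-4)
})

test_that("mixture conversion is conserved and monotone within the window", {
  mix <- lignin_curve()
  x <- conversion_curve(mix)
  expect_true(all(diff(x) >= -1e-12))
  expect_lte(pracma::trapz(mix$temperature, mix$rate), 1 + 1e-3)
})

test_that("doubling energy nodes leaves the rate curve unchanged within tolerance", {
  comp <- pseudo_component(1, dist_spec("logistic", 174341.2, 1334.2))
  r1 <- component_rate(comp, program5, n_nodes = 201)
  r2 <- component_rate(comp, program5, n_nodes = 402)
  expect_lt(max(abs(r1$rate - r2$rate)) / max(r1$rate), 1e-4)
})

test_that("faster heating shifts the peak to higher temperature (thermal hysteresis)", {
  spec <- dist_spec("gaussian", 178648.8, 1632)
  p10 <- heating_program(c_per_min_to_k_per_s(10))
  tp5 <- peak_temperature(component_rate(pseudo_component(1, spec), program5))
  tp10 <- peak_temperature(component_rate(pseudo_component(1, spec), p10))
  expect_gt(tp10, tp5)
})

test_that("inner-integral start sensitivity: 22 C vs 200 C start shifts the peak < 1%", {
  spec <- dist_spec("gaussian", 178648.8, 1632)
  from_ambient <- heating_program(t_start = celsius_to_kelvin(22))
  from_window <- heating_program(t_start = celsius_to_kelvin(200))
  t <- default_grid()
  tp1 <- peak_temperature(component_rate(pseudo_component(1, spec), from_ambient, t))
  tp2 <- peak_temperature(component_rate(pseudo_component(1, spec), from_window, t))
  expect_lt(abs(tp1 - tp2) / tp1, 0.01)
})
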