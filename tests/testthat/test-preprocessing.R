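make_tg <- function(n = 200, t_lo = 295.15, t_hi = 873.15,
                    mass = NULL, hf = NULL) {
  tt <- seq(t_lo, t_hi, length.out = n)
  if (is.null(mass)) mass <- seq(15, 3, length.out = n)
  if (is.null(hf)) hf <- rep(0, n)
  thermogram(time = (tt - tt[1]) / (5 / 60), temperature = tt,
             mass = mass, heat_flow = hf)
}

test_that("savitzky-golay reproduces polynomials and validates arguments", {
  x <- seq(0, 10, length.out = 101)
  expect_equal(savitzky_golay(rep(3.7, 50)), rep(3.7, 50))
  y <- 2 * x^3 - 5 * x^2 + x - 7
  expect_lt(max(abs(savitzky_golay(y, 21, 3) - y)), 1e-10)
  expect_error(savitzky_golay(y, 20, 3), "odd")
  expect_error(savitzky_golay(y, 3, 3), "exceed")
  expect_error(savitzky_golay(y, 203, 3), "length")
})

test_that("savitzky-golay is linear and reduces seeded noise", {
  set.seed(11)
  a <- rnorm(80); b <- rnorm(80)
  expect_equal(savitzky_golay(2 * a + 3 * b, 11, 2),
               2 * savitzky_golay(a, 11, 2) + 3 * savitzky_golay(b, 11, 2),
               tolerance = 1e-12)

  x <- seq(0, 4 * pi, length.out = 400)
  clean <- sin(x)
  set.seed(7)
  noisy <- clean + rnorm(400, 0, 0.05)
  sm <- savitzky_golay(noisy, 21, 3)
  expect_lt(sqrt(mean((sm - clean)^2)), sqrt(mean((noisy - clean)^2)))
})

test_that("conversion from mass hits the window anchors", {
  tg <- make_tg()
  w <- c(celsius_to_kelvin(200), celsius_to_kelvin(600))
  x <- conversion_from_mass(tg, w)
  m0 <- stats::approx(tg$temperature, tg$mass, w[1])$y
  m_inf <- stats::approx(tg$temperature, tg$mass, w[2])$y
  i_mid <- which.min(abs(tg$mass - (m0 + m_inf) / 2))
  expect_close(stats::approx(tg$temperature, x, w[1])$y, 0, 1e-9)
  expect_close(stats::approx(tg$temperature, x, w[2])$y, 1, 1e-9)
  expect_close(x[i_mid], 0.5, 0.01)

  flat <- make_tg(mass = rep(10, 200))
  expect_error(conversion_from_mass(flat, w), "degenerate")
})

test_that("temperature derivative: exactness, oracle recovery, grid errors", {
  tt <- seq(300, 800, length.out = 211)
  d <- derivative_wrt_temperature(3.5 * tt - 2, tt)
  expect_equal(d$derivative, rep(3.5, 211), tolerance = 1e-9)

  # recover a simulated model's dx/dT from its conversion curve
  prog <- heating_program()
  grid <- default_grid()
  r <- single_energy_rate(178648.8, 1.67e13, prog, grid)
  x <- pracma::cumtrapz(grid, r)[, 1]
  dx <- derivative_wrt_temperature(x, grid)$derivative
  expect_lt(max(abs(dx - r)) / max(r), 0.01)

  expect_error(derivative_wrt_temperature(1:10, rev(seq_len(10))), "increasing")
  # exact duplicates collapse by averaging
  d2 <- derivative_wrt_temperature(c(1, 2, 4, 4, 5), c(1, 2, 3, 3, 4))
  expect_length(d2$temperature, 4)
})

test_that("window truncation keeps exactly the in-range points", {
  tg <- make_tg()
  all_kept <- truncate_window(tg, min(tg$temperature), max(tg$temperature))
  expect_equal(all_kept$mass, tg$mass)

  w <- truncate_window(tg, celsius_to_kelvin(200), celsius_to_kelvin(600))
  expect_gte(min(w$temperature), celsius_to_kelvin(200) - 1e-6)
  # count agrees with a direct scan
  n_scan <- sum(tg$temperature >= celsius_to_kelvin(200) &
                tg$temperature <= celsius_to_kelvin(600))
  expect_length(w$temperature, n_scan)
  expect_error(truncate_window(tg, 1000, 1200), "retains no points")
  expect_error(truncate_window(tg, 600, 500), "t_lo < t_hi")
})

test_that("replicate averaging: identity, symmetry, variance reduction", {
  tg <- make_tg()
  avg1 <- average_replicates(list(tg, tg))
  ref <- stats::approx(tg$temperature, tg$mass, avg1$temperature)$y
  expect_equal(avg1$mass, ref, tolerance = 1e-9)

  # +delta / -delta perturbations cancel
  up <- tg; up$heat_flow <- tg$heat_flow + 0.7
  dn <- tg; dn$heat_flow <- tg$heat_flow - 0.7
  avg2 <- average_replicates(list(up, dn))
  expect_equal(avg2$heat_flow, rep(0, length(avg2$heat_flow)), tolerance = 1e-9)

  # averaging two noisy realizations beats either replicate
  fx <- cellulose_fixture()
  truth <- cellulose_curve()
  reps <- fixture_replicates(fx, noise_spec(seed = 3))
  rmse_dtg <- function(tg_in) {
    prep <- preprocess_thermogram(tg_in)
    ref <- stats::approx(truth$temperature, truth$rate, prep$dtg$temperature)$y
    sqrt(mean((prep$dtg$rate - ref)^2))
  }
  e_avg <- rmse_dtg(average_replicates(reps))
  expect_lt(e_avg, rmse_dtg(reps[[1]]))
  expect_lt(e_avg, rmse_dtg(reps[[2]]))
})

test_that("replicates with different loadings average on the conversion scale", {
  fx <- cellulose_fixture()
  t1 <- simulate_thermogram(fx$model, m0 = 10, m_inf = 1.3,
                            enthalpy = fx$enthalpy, noise = noise_free())
  t2 <- simulate_thermogram(fx$model, m0 = 20, m_inf = 2.6,
                            enthalpy = fx$enthalpy, noise = noise_free())
  avg <- average_replicates(list(t1, t2))
  x <- conversion_from_mass(avg)
  x1 <- conversion_from_mass(truncate_window(t1, min(avg$temperature),
                                             max(avg$temperature)))
  expect_lt(max(abs(x - x1)), 1e-6)
  expect_error(average_replicates(list(make_tg(t_lo = 300, t_hi = 400),
                                       make_tg(t_lo = 500, t_hi = 600))),
               "overlap")
})

test_that("noise-free pipeline reproduces the forward model within 2% of peak", {
  fx <- cellulose_fixture()
  tg <- simulate_thermogram(fx$model, m0 = fx$m0, m_inf = fx$m_inf,
                            enthalpy = fx$enthalpy, noise = noise_free())
  prep <- preprocess_thermogram(tg)
  truth <- cellulose_curve()
  ref <- stats::approx(truth$temperature, truth$rate, prep$dtg$temperature)$y
  expect_lt(max(abs(prep$dtg$rate - ref), na.rm = TRUE), 0.02 * max(ref, na.rm = TRUE))
})

test_that("truncation and differentiation commute away from window edges", {
  tg <- make_tg(n = 400, mass = 15 - 12 * pnorm(seq(295.15, 873.15,
                                                    length.out = 400), 600, 30))
  w <- c(celsius_to_kelvin(250), celsius_to_kelvin(550))
  d_then_t <- derivative_wrt_temperature(tg$mass, tg$temperature)
  keep <- d_then_t$temperature >= w[1] & d_then_t$temperature <= w[2]
  a <- d_then_t$derivative[keep]
  tr <- truncate_window(tg, w[1], w[2])
  b <- derivative_wrt_temperature(tr$mass, tr$temperature)$derivative
  interior <- seq(3, length(a) - 2)
  expect_equal(a[interior], b[interior], tolerance = 1e-9)
})
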