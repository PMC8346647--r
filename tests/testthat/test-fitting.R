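test_that("residuals vanish at the generating parameters and sum like a plain loop", {
  cv <- cellulose_curve()
  model <- cellulose_fixture()$model
  r <- residual_vector(model, cv)
  expect_lt(max(abs(r)), 1e-6 * max(cv$rate))

  # all-zero simulation leaves the data as the residual
  null_model <- one_comp_model("gaussian", 500, 1)  # inert inside the window
  r0 <- residual_vector(null_model, cv)
  expect_lt(max(abs(r0 - cv$rate)), 1e-12)

  # sum of squares matches naive re-summation
  ss <- 0
  for (i in seq_along(r)) ss <- ss + r[i] * r[i]
  expect_equal(sum(r^2), ss)
})

test_that("r_squared matches hand arithmetic and flags degenerate input", {
  obs <- c(1, 2, 3, 4, 10)
  fit <- c(1.1, 1.9, 3.2, 3.9, 9.5)
  ss_res <- sum((obs - fit)^2)           # 0.01+0.01+0.04+0.01+0.25
  ss_tot <- sum((obs - mean(obs))^2)     # mean 4: 9+4+1+0+36
  expect_equal(r_squared(obs, fit), 1 - ss_res / ss_tot)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 5)), 0)
  expect_error(r_squared(rep(2, 5), fit), "zero-variance")
  a <- rate_curve(1:10 + 300, rep(0:1, 5), "measured")
  b <- rate_curve(1:10 + 400, rep(0:1, 5), "measured")
  expect_error(r_squared(a, b), "common grid")
})

test_that("peak-based initialization inverts the peak condition", {
  prog <- heating_program()
  e_true <- 178648.8
  t <- default_grid()
  cv <- rate_curve(t, single_energy_rate(e_true, 1.67e13, prog, t), "measured")
  init <- initialize_from_peaks(cv, 1)
  expect_false(attr(init, "fallback"))
  expect_close(init$e_mean, e_true, 1000)
  expect_equal(sum(init$fractions), 1)

  # four-stage curve: four inits ordered by temperature, fractions on simplex
  lig <- lignin_curve()
  init4 <- initialize_from_peaks(lig, 4)
  expect_length(init4$e_mean, 4)
  expect_true(all(diff(init4$t_peaks) > 0))
  expect_close(sum(init4$fractions), 1, 1e-12)

  # flat curve falls back and says so
  flat <- rate_curve(t, rep(0, length(t)), "measured")
  init_f <- initialize_from_peaks(flat, 2)
  expect_true(attr(init_f, "fallback"))
  expect_length(init_f$e_mean, 2)
})

test_that("single-component round trips recover parameters across families", {
  # parameterized recovery over the corner cases of the (E, sigma) box
  cases <- expand.grid(family = c("gaussian", "logistic", "gumbel", "cauchy"),
                       e_kJ = c(150, 220), s_kJ = c(1, 12),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    truth <- one_comp_model(cs$family, cs$e_kJ, cs$s_kJ)
    cv <- mixture_rate(truth)
    cv$source <- "measured"
    cfg <- fit_config(1, cs$family, max_restarts = 0)
    fit <- fit_daem(cv, cfg)
    e_hat <- fit$model$components[[1]]$dist$e_mean / 1000
    s_hat <- fit$model$components[[1]]$dist$sigma / 1000
    expect_lt(abs(e_hat - cs$e_kJ) / cs$e_kJ, 0.005,
              label = sprintf("%s E=%g s=%g: E_hat=%.3f", cs$family, cs$e_kJ,
                              cs$s_kJ, e_hat))
    expect_lt(abs(s_hat - cs$s_kJ) / cs$s_kJ, 0.05,
              label = sprintf("%s E=%g s=%g: s_hat=%.3f", cs$family, cs$e_kJ,
                              cs$s_kJ, s_hat))
    expect_gt(fit$r_squared, 0.9999)   # self-fit quality
  }
})

test_that("recovered cellulose energy is stable under 1% peak-height noise", {
  cv <- cellulose_curve()
  peak <- max(cv$rate)
  cfg <- fit_config(1, "gaussian", max_restarts = 0)
  for (seed in 1:20) {
    noisy <- cv
    noisy$rate <- cv$rate + withr::with_seed(seed,
      stats::rnorm(length(cv$rate), 0, 0.01 * peak))
    fit <- fit_daem(noisy, cfg)
    expect_close(fit$model$components[[1]]$dist$e_mean, 178648.8, 2000)
  }
})

test_that("replicate curves are fit jointly via concatenated residuals", {
  fx <- cellulose_fixture()
  reps <- fixture_replicates(fx, noise_spec(seed = 21))
  curves <- lapply(reps, function(tg) preprocess_thermogram(tg)$dtg)
  cfg <- fit_config(1, "gaussian", max_restarts = 0)
  # residual vector covers both experiments
  r <- residual_vector(fx$model, curves, cfg)
  expect_length(r, sum(lengths(lapply(curves, `[[`, "rate"))))
  fit <- fit_daem(curves, cfg)
  expect_close(fit$model$components[[1]]$dist$e_mean, 178648.8, 2000)
  expect_gt(fit$r_squared, 0.99)
})

test_that("fit results are deterministic and respect the simplex constraint", {
  cv <- cellulose_curve()
  cfg <- fit_config(1, "gaussian", max_restarts = 2, seed = 7)
  f1 <- fit_daem(cv, cfg)
  f2 <- fit_daem(cv, cfg)
  expect_identical(fit_parameters(f1), fit_parameters(f2))
  expect_true(f1$converged)

  lig_cfg <- fit_config(2, "gaussian", max_restarts = 0)
  f3 <- fit_daem(lignin_curve(), lig_cfg)
  expect_lt(abs(sum(vapply(f3$model$components, `[[`, 1, "fraction")) - 1), 1e-8)
  expect_length(f3$per_component_curves, 2)
})

test_that("model scan improves monotonically in n and prefers parsimony on ties", {
  # two-stage synthetic so the scan is cheap and the truth is known
  truth <- daem_model(list(
    pseudo_component(0.55, dist_spec("gaussian", 165e3, 3e3)),
    pseudo_component(0.45, dist_spec("gaussian", 200e3, 5e3))))
  cv <- mixture_rate(truth)
  cv$source <- "measured"
  cfg <- fit_config(1, "gaussian", max_restarts = 0)
  scan <- model_scan(cv, 1:3, "gaussian", cfg)
  s <- scan$summary[order(scan$summary$n_components), ]
  best_by_n <- cummax(s$r_squared)
  expect_true(all(diff(best_by_n) >= -1e-12))
  expect_gt(s$r_squared[s$n_components == 2], s$r_squared[s$n_components == 1])
  # n = 3 cannot beat n = 2 by more than the tie tolerance on noise-free data
  sel <- scan_select(scan)
  expect_equal(attr(sel, "n_components"), 2)

  # one-stage data: n = 1 selected under the tie rule
  cv1 <- cellulose_curve()
  scan1 <- model_scan(cv1, 1:2, "gaussian", cfg)
  expect_equal(attr(scan_select(scan1), "n_components"), 1)
})

test_that("the generating family wins the family comparison on synthetic data", {
  cv <- cellulose_curve()   # gaussian-generated
  cfg <- fit_config(1, "gaussian", max_restarts = 0)
  scan <- model_scan(cv, 1, c("gaussian", "logistic", "gumbel", "cauchy"), cfg)
  s <- scan$summary
  expect_equal(s$family[which.max(s$r_squared)], "gaussian")
  expect_true(all(s$r_squared[s$family == "gaussian"] >=
                  s$r_squared[s$family == "logistic"]))
})

test_that("scan records individual failures without aborting", {
  cv <- cellulose_curve()
  short <- rate_curve(cv$temperature[1:3], cv$rate[1:3], "measured")
  cfg <- fit_config(1, "gaussian", max_restarts = 0)
  scan <- suppressWarnings(model_scan(short, 1, "gaussian", cfg))
  expect_false(any(is.na(scan$summary$error)) && nrow(scan$summary) == 0)
})
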