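# shared fixtures, memoized: several files re-use the same noise-free
# reference curves, and simulating them once keeps the suite fast
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

noise_free <- function() noise_spec(mass_noise_sd = 0, heatflow_noise_sd = 0,
                                    baseline_drift = 0)

cellulose_curve <- function(family = "gaussian") {
  memo(paste0("cell_", family), {
    cv <- mixture_rate(cellulose_fixture(family)$model)
    cv$source <- "measured"
    attr(cv, "components") <- NULL
    cv
  })
}

lignin_curve <- function(family = "gaussian") {
  memo(paste0("lig_", family), {
    cv <- mixture_rate(lignin_fixture(family)$model)
    cv$source <- "measured"
    attr(cv, "components") <- NULL
    cv
  })
}

# single-component model on an arbitrary family, for parameterized cases
one_comp_model <- function(family, e_kJ, s_kJ, k0 = 1.67e13,
                           program = heating_program()) {
  daem_model(list(pseudo_component(1, dist_spec(family, e_kJ * 1000, s_kJ * 1000), k0)),
             program)
}

expect_close <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("|%s - %s| <= %s",
                              paste(signif(actual, 8), collapse = ","),
                              paste(signif(expected, 8), collapse = ","), tol))
}
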