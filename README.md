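# daemfit

Kinetic analysis of slow biomass pyrolysis from simultaneous TGA/DSC
measurements, using the multi-distribution **Distributed Activation Energy
Model (DAEM)**.

Thermogravimetric pyrolysis of lignocellulosic materials is a multi-step
process: the derivative mass-loss (DTG) curve of lignin, for example, is a
superposition of overlapping decomposition stages, and the heat-flow (DSC)
channel shows that those stages differ in reaction enthalpy. `daemfit`
decomposes such traces into *pseudo-components*, each a continuum of
parallel irreversible first-order reactions whose activation energies
follow a density F(E):

    dx/dT = Σᵢ cᵢ ∫ (k₀/β) exp[−(E/RT + (k₀/β) ∫_{T₀}^{T} e^{−E/RT′} dT′)] Fᵢ(E) dE

with mass-based conversion x = (m₀ − m)/(m₀ − m∞), heating rate β, and a
pre-exponential factor fixed at k₀ = 1.67 × 10¹³ s⁻¹ to defeat the kinetic
compensation effect. Four families are available for F(E) — Gaussian,
Logistic, Gumbel, Cauchy — and (cᵢ, Ēᵢ, σᵢ) are estimated by bounded
nonlinear least squares against the measured DTG curve, with fractions
constrained to the simplex by construction. The number of pseudo-components
is rationalized by concordance between DTG peaks and DSC thermal events:
a heat event with no mass-loss counterpart marks a stage buried under a
shoulder (char conversion is the classic case).

The package covers the full workflow: forward simulation, thermogram
preprocessing (Savitzky–Golay smoothing, conversion normalization,
differentiation, replicate averaging), fitting and model scans, DTG/DSC
concordance heuristics, a synthetic TGA/DSC generator for testing, and
delimited-text I/O.

## Worked example

Simulate a duplicated cellulose TGA/DSC experiment (published kinetics,
5 °C min⁻¹, 22–600 °C, instrument noise), preprocess, check the component
count against the DSC channel, and refit the DAEM:

```r
library(daemfit)

fx   <- cellulose_fixture()                       # published cellulose kinetics
reps <- fixture_replicates(fx, noise_spec(seed = 42))   # two noisy replicates
prep <- preprocess_thermogram(average_replicates(reps))

suggest_component_count(prep$dtg, prep$dsc_derivative)
#> $n_components
#> [1] 1
#> $report
#>   channel temperature_K temperature_C sign matched
#> 1     dtg      600.1500      327.0000 <NA>    TRUE
#> 2     dsc      600.1866      327.0366 endo    TRUE

fit <- fit_daem(prep$dtg, fit_config(1, "gaussian", seed = 42))
fit
#> <fit_result> R^2 = 0.9994, residual norm = 4.014e-03, converged
#> <daem_model> 1 pseudo-component(s), beta = 5.0000 C min^-1
#>   [1] c = 1.0000  gaussian(E = 178.6481, sigma = 1.6226 kJ mol^-1)  k0 = 1.67e+13 s^-1
```

Reading the output: one mass-loss peak at 327 °C is matched by one
endothermic DSC event at the same temperature, so a single pseudo-component
suffices; the fit then recovers a mean activation energy of
178.65 kJ mol⁻¹ with a narrow spread (σ ≈ 1.6 kJ mol⁻¹) — cellulose
devolatilization behaving as one nearly uniform endothermic reaction. The
recovered parameters match the generating values (Ē = 178.6488,
σ = 1.6320 kJ mol⁻¹) to within the noise.

For multi-stage materials, `lignin_fixture()` provides a four-component
reference model, `model_scan()` compares component counts and distribution
families by R², and `run_pipeline(run_config(...))` drives the whole
workflow from thermogram CSVs to parameter tables and reports.

## Layout

- `R/` — distributions, forward model, preprocessing, fitting,
  concordance, synthetic data, I/O
- `src/` — batched DAEM rate kernel (Rcpp)
- `vignettes/daem-kinetics.Rmd` — model, numerical choices, design
  decisions, limitations
- `tests/testthat/` — unit, property, and round-trip suites
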