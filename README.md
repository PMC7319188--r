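# simexpo

Monte Carlo assessment of what exposure measurement error does to health
effect estimates when modeled air-pollutant concentrations (land use
regression, dispersion, hybrids) replace true concentrations in a
multilevel epidemiological analysis.

**Who it is for:** environmental epidemiologists and exposure modellers who
want to translate exposure-model validation results into statements about
bias, confidence-interval coverage and power of the downstream health
analysis — not just daily prediction accuracy.

## The model at its core

Daily event counts in small areas follow a multilevel Poisson model that
jointly estimates a short-term (within-area, daily) and a long-term
(between-area, period-mean) effect via the within/between decomposition of
the exposure:

    Y_it ~ Poisson(λ_it)
    log λ_it = log(pop_i) + β0 + u_i + β_ST (X_it − X̄_i) + β_LT X̄_i,
    u_i ~ N(0, σu²)

Measurement error in a modeled exposure Z is parameterized by four
quantities — the Pearson correlation ρ and variance ratio λ = var(Z)/var(X)
of model versus truth, computed separately for the temporal component
(ρ_T, λ_T; daily deviations within areas) and the spatial component
(ρ_S, λ_S; long-term means between areas). For small CRFs the induced
multiplicative bias is

    E[β̂_ST]/β_ST ≈ ρ_T/√λ_T      E[β̂_LT]/β_LT ≈ ρ_S/√λ_S

so classical error (λ > 1, ρ = 1/√λ) attenuates towards the null, while
Berkson error (λ < 1, ρ = √λ) leaves estimates unbiased but inflates
standard errors. The package simulates a "true" spatio-temporal
concentration field, plants any (ρ, λ) structure into a pseudo-modeled
exposure (additively, or multiplicatively via the log scale), refits the
model over replicates, and reports bias, coverage and power. A validation
module estimates (ρ_T, ρ_S, λ_T, λ_S) from real paired model–monitor data
with instrument-error disattenuation, and computes the standard metrics MB,
NMB, NMGE, RMSE and FAC2.

## Worked example

A classical-like error structure (ρ_T = 0.7, λ_T = 1.8, ρ_S = 0.6,
λ_S = 2.2), 100 areas × 150 days × 100 replicates:

```r
library(simexpo)
spec <- scenario_spec(
  name  = "classical_like",
  error = error_params(rho_T = 0.7, rho_S = 0.6, lambda_T = 1.8,
                       lambda_S = 2.2, pollution_model = "LUR"),
  crf   = crf_set(sigma_u = 0),
  n_areas = 100, n_days = 150, n_sims = 100, base_seed = 42)
res <- run_scenario(spec, fit_method = "glm")
res$summary
#> <performance_summary> 100 replicates (0 excluded)
#>  horizon true_value mean_est  mean_se pct_bias abs_bias bias_flag coverage
#>       ST       0.03  0.01615 0.004057   -46.16 -0.01385   percent        5
#>       LT       0.08  0.03241 0.008865   -59.49 -0.04759   percent        0
#>  power t_stat  t_pvalue n_effective
#>     97 -35.47 4.336e-58         100
#>     92 -48.94 3.522e-71         100
```

Reading it: the true short-term effect is 0.03 per 10 µg/m³ but the mean
estimate is 0.0162 — a −46% bias, right where the attenuation law puts it
(0.7/√1.8 = 0.52, i.e. −48%). The long-term effect attenuates by −59%
(0.6/√2.2 = 0.41). Coverage of the 95% intervals collapses (5% and 0%):
classical-like error does not just shrink estimates, it makes the analysis
confidently wrong.

Estimating error parameters from paired model–monitor data with known
instrument noise (here: synthetic pairs with planted ρ_T = 0.8, ρ_S = 0.9,
λ_T = 1.5, λ_S = 1.2 and instrument sd 2 µg/m³):

```r
net <- make_monitor_network(c(background = 20), n_days = 730, seed = 1)
vp  <- make_validation_pairs(net,
         error_params(rho_T = 0.8, rho_S = 0.9, lambda_T = 1.5, lambda_S = 1.2),
         instrument_sd = 2, seed = 2)
estimate_error_params(vp, site_type = "background")
#> <error_param_estimate> 20 sites, 14600 records
#> <error_params> rho_T=0.7972834 rho_S=0.8644879 lambda_T=1.48699 lambda_S=1.006725 ...
#>   naive: rho_T=0.785 rho_S=0.864 lambda_T=1.443 lambda_S=1.007

standard_metrics(vp)
#> <validation_stats> 20 sites; site-type averages:
#>   site_type n_sites    MB    NMB  NMGE RMSE  FAC2
#>  background      20 0.617 0.0168 0.177 9.14 0.973
```

The corrected ρ_T (0.797) and λ_T (1.487) recover the planted 0.8 and 1.5;
the naive values (0.785, 1.443) are attenuated by the instrument noise.
(Spatial estimates at 20 sites carry sampling error of ~0.05; the package's
acceptance tests average 100 seeds at 47 sites to verify ±0.02 recovery.)

Manifests of many scenarios run via YAML
(`run_manifest("manifest.yaml", out_dir = "results")`; template in
`inst/extdata/manifest_template.yaml`), or from the shell via
`inst/cli/simexpo` with subcommands `run`, `simulate`, `validate`, `synth`.

## Documentation

See the methods vignette
(`vignettes/measurement-error-simulation.Rmd`) for the model, the error
injection algebra, the instrument-error correction, default parameter
rationale, and what the synthetic world does and does not establish.
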