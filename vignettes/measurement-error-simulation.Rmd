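---
title: "Assessing exposure measurement error in multilevel air pollution epidemiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing exposure measurement error in multilevel air pollution epidemiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simexpo)
```

## The problem

Epidemiological analyses of air pollution and health increasingly use
concentrations predicted by exposure models — land use regression (LUR),
dispersion models, or hybrids — in place of measured concentrations. The
prediction error this introduces is a mixture of classical-like error (from
parameter estimation) and Berkson-like error (from oversmoothing the
pollutant surface). Standard validation metrics (mean bias, RMSE, FAC2)
describe how well the model predicts daily concentrations, but say little
about what the error does to a *health effect estimate* sitting at the end
of a complex analysis: attenuation towards the null, loss of confidence
interval coverage, or loss of power.

`simexpo` quantifies that downstream impact by Monte Carlo simulation. The
key insight it operationalizes is that the impact of model error on a
log-linear health analysis is governed not by prediction accuracy per se but
by two second-moment summaries of the model-versus-truth relationship,
computed separately for the *spatial* component (between-area long-term
means) and the *temporal* component (within-area daily deviations): the
Pearson correlation `rho` and the variance ratio `lambda` (model/true). Pure
classical error gives `lambda > 1` with `rho = 1/sqrt(lambda)`; pure Berkson
error gives `lambda < 1` with `rho = sqrt(lambda)`; real exposure models
fall elsewhere in the `(rho, lambda)` plane.

## The simulation pipeline

Each scenario runs four steps per replicate.

**Step 1 — truth.** `simulate_truth()` draws "true" daily concentrations
at each small-area centroid from

$$X_{it} = \mu + a_i + A\cos(2\pi t/P) + c_t + e_{it},$$

with \(a_i\) a zero-mean Gaussian spatial field with exponential covariance
\(\sigma_S^2\exp(-d_{ij}/\phi)\), \(c_t\) a stationary AR(1) common daily
shock (lag-1 coefficient \(\rho_{AR}\), stationary sd \(\sigma_C\)), and
\(e_{it}\) iid noise (sd \(\sigma_E\)). This is deliberately the *minimal*
structure carrying the moments that matter downstream: a spatial variance
with distance decay, a temporal variance with seasonality and
autocorrelation, and nothing else. Richer forms (Matérn covariances,
multiple harmonics) would not change what the error injection sees.
Simulated concentrations can go negative on the natural scale; they are
retained, not truncated, because truncation would distort the
\((\rho,\lambda)\) calibration and the log-linear outcome model tolerates
them.

Defaults describe an urban-background NO2-like pollutant
(`mu = 40`, `sigma_S = 5`, `phi_km = 10`, `amp = 8`, `rho_AR = 0.7`,
`sigma_C = 6`, `sigma_E = 8`, all in µg/m³ except the correlation), giving a
day-to-day deviation sd of about 11.5 µg/m³ — a realistic magnitude.

**Step 2 — outcomes.** `simulate_outcomes()` draws daily event counts from

$$Y_{it}\sim\text{Poisson},\quad
\log\lambda_{it} = \log(\text{pop}_i) + \beta_0 + u_i +
\beta_{ST} D_{it} + \beta_{LT}\bar X_i,$$

where \(\bar X_i\) is the area's period mean, \(D_{it}\) the daily
deviation, and \(u_i\sim N(0,\sigma_u^2)\) an area random intercept. The
default CRFs (`beta0 = -7`, `beta_ST = 0.003`, `beta_LT = 0.008`,
`sigma_u = 0.05`) are **illustrative, not estimates from any study**. They
were chosen once, a priori, so that both coefficients have relative
standard error below ~0.2 at the desk-scale default of 100 areas x 365
days; that makes a ±3% Monte Carlo percent-bias check meaningful at 200
replicates. With realistic mortality rates and CRFs, detecting a 3% bias
would require the full-scale design (1,000 areas x 1,826 days x 1,000
replicates), which is available by configuration but takes hours.

**Step 3 — error injection.** `inject_error()` builds the pseudo-modeled
field from the truth's realized components:

$$\bar Z_i = m + \rho_S\sqrt{\lambda_S}(\bar X_i - m)
  + \sqrt{\lambda_S\sigma_S^2(1-\rho_S^2)}\,\eta_i,\qquad
E_{it} = \rho_T\sqrt{\lambda_T}D_{it}
  + \sqrt{\lambda_T\sigma_T^2(1-\rho_T^2)}\,\nu_{it},$$

with \(\sigma_S^2,\sigma_T^2\) the *sample* moments of the realized truth
(so the \(\lambda\) calibration refers to the data actually used in that
replicate), and iid standard normal \(\eta_i,\nu_{it}\). Injection noise is
independent across areas and days: heteroscedastic or spatially correlated
model error is out of scope, mirroring the error model being studied. The
pseudo-model mean is anchored to the truth mean — mean shifts do not bias
log-linear slopes — with a configurable `mean_offset` for sensitivity runs.

Proportional (multiplicative) error scenarios run Steps 1-3 on log
concentrations (`truth_params_log()`, `error_scale = "proportional"`) and
exponentiate at the Step 2/Step 4 boundaries.

**Step 4 — refit.** `fit_multilevel_poisson()` regresses the counts on the
pseudo-modeled exposure entered twice (within-area deviation and centred
area mean — the Mundlak/within-between decomposition, the minimal structure
that yields both a short-term and a long-term effect from a single fit),
with an area random intercept estimated by Laplace approximation
(`lme4::glmer`, warm-started from a Poisson GLM). A singular or failed GLMM
falls back to a plain Poisson GLM — exact when \(\sigma_u = 0\) — and the
path taken is recorded per replicate. Estimates and Wald SEs are reported
per 10 µg/m³.

`run_scenario()` iterates the four steps with deterministic per-replicate
seeds (stride-4 derivation from the scenario base seed, scenarios in a
manifest spaced \(2^{20}\) apart), and `summarize_performance()` reports
mean estimate, mean SE, percent bias, 95% CI coverage, power at the 5%
level, and a one-sample t-test of the estimates against the truth.

## What theory predicts, and what the tests check

For small CRFs, the probability limit of the fitted coefficient on each
injected component is the projection coefficient, so the multiplicative
bias is

$$\frac{E[\hat\beta_{ST}]}{\beta_{ST}} \approx \frac{\rho_T}{\sqrt{\lambda_T}},
\qquad
\frac{E[\hat\beta_{LT}]}{\beta_{LT}} \approx \frac{\rho_S}{\sqrt{\lambda_S}}.$$

The acceptance suite verifies this on a 3x3 grid per horizon (±5
percentage points at 200 replicates), including its qualitative corollaries:
bias *away* from the null when a high correlation is paired with a low
variance ratio, substantial bias *towards* the null when a high variance
ratio is paired with a low correlation, and near-unbiasedness with inflated
SEs under Berkson structure. It also checks that direct classical injection
\(Z = X + U\) and its \((\rho,\lambda)=(1/\sqrt2, 2)\) encoding produce the
same bias, that identity error is calibrated (bias within ±3%, coverage in
the binomial band [91, 98]% at 200 replicates), and that under the null the
type-I error is ~5%.

## The validation side

`estimate_error_params()` computes \((\rho_T,\rho_S,\lambda_T,\lambda_S)\)
from paired model-monitor daily series. Monitor readings carry instrument
noise, so naive moments compare model with *monitored* rather than *true*
concentrations; the standard errors-in-variables disattenuation is applied:
with \(v_O\) the monitor deviation variance, \(v_I\) the known instrument
noise variance and \(r\) the observed correlation,

$$\lambda_T = \frac{v_M}{v_O - v_I},\qquad
\rho_T = r\sqrt{\frac{v_O}{v_O - v_I}}.$$

The model side needs no correction. The spatial component applies the same
algebra to site period means with \(v_I\) divided by each site's number of
observation days — negligible for multi-year series, which is why the
correction matters mainly for the temporal component. Temporal deviations
are pooled across sites of a type after per-site centering (a per-site
variant is available via `pooled = FALSE`). A corrected correlation can
exceed 1 by sampling noise when the model is essentially the noise-free
truth; it is capped at ±1 with the uncapped value retained in the returned
object. If the stated instrument variance exceeds the observed variance the
estimator refuses, naming the component.

`make_validation_pairs()` manufactures paired data with *known* planted
\((\rho,\lambda)\) and instrument noise, which is how the estimator is
tested: at 47 background sites x 1,826 days with instrument sd 2 µg/m³,
corrected estimates recover the planted values within ±0.02 (correlations)
and ±5% (variance ratios) averaged over 100 seeds, while naive estimates
are measurably attenuated.

`standard_metrics()` computes MB, NMB, NMGE, RMSE and FAC2 per site and as
unweighted site-type averages; FAC2 uses the closed interval [0.5, 2], and
days with non-positive monitor values are excluded from FAC2 and the
normalized metrics with a reported count. `leave_out_split()` provides the
leave-10%-out partition bookkeeping used when validating exposure models
trained on monitor data.

## What the synthetic world does and does not establish

The generator emulates: a two-type monitoring network (background,
roadside) with seasonal, autocorrelated, spatially correlated daily series;
additive instrument noise; small-area geographies with ~1,500 residents per
area; and planted error structure. It does not emulate: real geography or
land use, heteroscedastic or spatially correlated model error, missingness
mechanisms other than MCAR, temporal confounders (season, day-of-week) in
the outcome model, or covariate confounding. A green acceptance suite
therefore establishes that the machinery is calibrated and that the
attenuation algebra holds in the stated world — not that any particular
real exposure model is good or bad. Estimates for real models come from
feeding real paired validation data to `estimate_error_params()` and the
resulting parameters to `run_scenario()`; the shipped
`manifest_template.yaml` contains placeholder grids spanning the
qualitative regimes, not estimates.

## Numerical choices and edge cases

- **Seeds.** Every random stage (geography, truth, outcomes, injection) has
  its own derived seed; fixed seeds give bit-identical outputs, and results
  are invariant to scenario execution order.
- **Duplicate centroids** make the spatial covariance singular; they are
  jittered by 1 m with a warning (or rejected via `on_duplicate =
  "error"`). A relative nugget of 1e-8 stabilises the Cholesky.
- **Rate overflow.** `simulate_outcomes()` errors if any log rate exceeds a
  cap (default 30), naming the offending cell, rather than silently
  producing astronomical counts.
- **Fallback hierarchy.** The design allows Laplace → penalized
  quasi-likelihood → GLM; the implemented ladder is Laplace → GLM. The only
  failure mode observed in this model class is the \(\sigma_u \to 0\)
  boundary, where the GLM is exact, so a PQL middle tier would add a
  dependency without adding robustness. `method_used` records the path.
- **Zero true CRF.** Percent bias is undefined; the summary flags the row
  and reports absolute bias instead of dividing by zero.
- **Non-convergence.** Replicates that error are logged and skipped; a
  scenario aborts if more than 10% fail.

## Known limitations

Single-pollutant, no covariates, no spatially structured model error, Wald
intervals only, and the desk-scale defaults trade Monte Carlo resolution
for runtime: percent-bias comparisons sharper than a few percentage points
need the full-scale configuration.
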