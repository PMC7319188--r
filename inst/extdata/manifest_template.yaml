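# simexpo scenario manifest template.
#
# The error grids below are PLACEHOLDERS spanning the qualitative regimes of
# interest, not estimates from any real validation study:
#   - identity          (rho = 1, lambda = 1): error-free reference
#   - classical-like    (rho < 1, lambda > 1): bias towards the null,
#                       undercoverage
#   - berkson-like      (rho = sqrt(lambda), lambda < 1): little bias,
#                       inflated SEs, reduced power
#   - high-rho/low-lambda (rho ~ 1, lambda < 1): small bias away from the null
# Replace them with estimates from your own validation data
# (estimate_error_params on paired model-monitor series).

root_seed: 20260909

defaults:
  pollutant: NO2
  outcome: all_cause
  site_type: background
  n_areas: 100
  n_days: 365
  n_sims: 200
  crf:
    beta0: -7.0
    beta_ST: 0.003
    beta_LT: 0.008
    sigma_u: 0.05
  truth:
    mu: 40
    sigma_S: 5
    phi_km: 10
    amp: 8
    rho_AR: 0.7
    sigma_C: 6
    sigma_E: 8

scenarios:
  - name: identity
    pollution_model: custom
    error: {rho_T: 1.0, rho_S: 1.0, lambda_T: 1.0, lambda_S: 1.0}
  - name: classical_like
    pollution_model: LUR
    error: {rho_T: 0.7, rho_S: 0.6, lambda_T: 1.8, lambda_S: 2.2}
  - name: berkson_like
    pollution_model: dispersion
    error: {rho_T: 0.84, rho_S: 0.77, lambda_T: 0.7, lambda_S: 0.6}
  - name: away_from_null
    pollution_model: hybrid2
    error: {rho_T: 0.95, rho_S: 0.95, lambda_T: 0.6, lambda_S: 0.7}
  - name: proportional_classical
    pollution_model: LUR
    error: {rho_T: 0.7, rho_S: 0.6, lambda_T: 1.8, lambda_S: 2.2,
            error_scale: proportional}
    # proportional error runs on log concentrations: every truth parameter
    # must be restated on the log scale (median 40, CV ~12% between areas)
    truth: {scale: log, mu: 3.6889, sigma_S: 0.12, phi_km: 10, amp: 0.2,
            rho_AR: 0.7, sigma_C: 0.15, sigma_E: 0.2}
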