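# Shared fixture builders. Everything is generated in code; no stored data.

tiny_geography <- function(n = 20, seed = 11) {
  make_geography(n_areas = n, extent_km = 20, population_mean = 1500,
                 seed = seed)
}

tiny_field <- function(n_areas = 20, n_days = 40, seed = 12, ...) {
  simulate_truth(tiny_geography(n_areas), truth_params(...), n_days,
                 seed = seed)
}

# a fast scenario: no random intercept in the data, plain-GLM fitting route
fast_spec <- function(name = "fast", n_areas = 30, n_days = 50, n_sims = 4,
                      base_seed = 5, error = error_params(), ...) {
  scenario_spec(name = name, error = error,
                crf = crf_set(sigma_u = 0),
                n_areas = n_areas, n_days = n_days, n_sims = n_sims,
                base_seed = base_seed, ...)
}

# hand-built validation_pairs object from explicit vectors
pairs_fixture <- function(site_id, site_type, day, monitor, model,
                          instrument_error_variance = 0,
                          scale = "additive") {
  ids <- unique(site_id)
  iev <- setNames(rep_len(instrument_error_variance, length(ids)), ids)
  structure(
    list(pairs = data.frame(site_id = site_id, site_type = site_type,
                            day = day, monitor = monitor, model = model,
                            stringsAsFactors = FALSE),
         instrument_error_variance = iev, scale = scale, planted = NULL),
    class = "validation_pairs"
  )
}

# build a fit_result by hand (for performance-summary oracles)
fit_stub <- function(est_ST, se_ST, est_LT, se_LT, converged = TRUE) {
  structure(list(est_ST = est_ST, se_ST = se_ST, est_LT = est_LT,
                 se_LT = se_LT, sigma_u_hat = 0, converged = converged,
                 n_obs = 100L, method_used = "stub"),
            class = "fit_result")
}
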