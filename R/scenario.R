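#' Define a simulation scenario
#'
#' A scenario bundles everything one Monte Carlo cell needs: labels
#' (pollutant, outcome, pollution model, site type), the error structure,
#' the concentration-response coefficients, the truth-model parameters, the
#' study dimensions, the replicate count and the base seed. Proportional
#' error scenarios must use a log-scale truth model (e.g.
#' [truth_params_log()]): the pipeline then runs end-to-end on the log scale
#' and back-transforms at the outcome-simulation and model-fitting
#' boundaries.
#'
#' Default dimensions are desk-scale (100 areas x 365 days x 200 replicates)
#' so a scenario runs in minutes; a full-scale study (1,000 areas x 1,826
#' days x 1,000 replicates) is configured by raising them.
#'
#' @param name scenario label (unique within a manifest).
#' @param pollutant,outcome,pollution_model,site_type free-text labels.
#' @param error an [error_params()] object.
#' @param crf a [crf_set()] object.
#' @param truth a [truth_params()] object.
#' @param n_areas,n_days study dimensions.
#' @param n_sims number of Monte Carlo replicates (>= 1).
#' @param base_seed integer base seed; replicate r uses seeds derived
#'   deterministically from it.
#' @param extent_km,population_mean geography settings.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = "scenario", pollutant = "NO2",
                          outcome = "all_cause", pollution_model = "custom",
                          site_type = "background",
                          error = error_params(), crf = crf_set(),
                          truth = truth_params(),
                          n_areas = 100, n_days = 365, n_sims = 200,
                          base_seed = 1L, extent_km = 50,
                          population_mean = 1500) {
  stopifnot(inherits(error, "error_params"), inherits(crf, "crf_set"),
            inherits(truth, "truth_params"))
  n_areas <- check_count(n_areas, "n_areas", min = 2L)
  n_days <- check_count(n_days, "n_days", min = 2L)
  n_sims <- check_count(n_sims, "n_sims", min = 1L)
  if (error$error_scale == "proportional" && truth$scale != "log") {
    stop("proportional-error scenarios require a log-scale truth model; ",
         "use truth_params_log() (parameters are then on the log scale)")
  }
  if (error$error_scale == "additive" && truth$scale != "natural") {
    stop("additive-error scenarios require a natural-scale truth model")
  }
  structure(
    list(name = name, pollutant = pollutant, outcome = outcome,
         pollution_model = pollution_model, site_type = site_type,
         error = error, crf = crf, truth = truth,
         n_areas = n_areas, n_days = n_days, n_sims = n_sims,
         base_seed = as.integer(base_seed), extent_km = extent_km,
         population_mean = population_mean),
    class = "scenario_spec"
  )
}

#' Run one scenario: replicate Steps 1-4 and summarize
#'
#' Executes `n_sims` replicates of the full pipeline — simulate truth,
#' simulate outcomes from the truth, inject error, fit the multilevel model
#' to the pseudo-modeled exposure — and aggregates the fits with
#' [summarize_performance()]. The geography is drawn once per scenario;
#' replicate `r` derives its truth/outcome/injection seeds deterministically
#' from `base_seed` (stride 4), so results are bit-identical across runs and
#' independent of execution order.
#'
#' Replicates whose fit errors out are logged and skipped; the scenario
#' aborts if more than `max_fail` of replicates fail.
#'
#' @param spec a [scenario_spec()].
#' @param fit_method passed to [fit_multilevel_poisson()] (`"auto"`,
#'   `"glmm"`, `"glm"`).
#' @param nAGQ Laplace/AGQ setting for the GLMM.
#' @param max_fail maximum tolerated failed-replicate fraction (default 0.1).
#' @param progress print a dot per 50 replicates.
#' @return object of class `scenario_result`: list with `summary`
#'   (a `performance_summary`), `fits` (per-replicate data.frame), `spec`,
#'   `failures` (data.frame of replicate, message).
#' @export
run_scenario <- function(spec, fit_method = "auto", nAGQ = 1L,
                         max_fail = 0.1, progress = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  geo <- make_geography(spec$n_areas, spec$extent_km, spec$population_mean,
                        seed = derive_seed(spec$base_seed, 0L, stage = 0L))
  fits <- vector("list", spec$n_sims)
  fail <- list()
  for (r in seq_len(spec$n_sims)) {
    res <- tryCatch({
      fld <- simulate_truth(geo, spec$truth, spec$n_days,
                            seed = derive_seed(spec$base_seed, r, stage = 1L))
      out <- simulate_outcomes(fld, spec$crf, geo,
                               seed = derive_seed(spec$base_seed, r, stage = 2L))
      z <- inject_error(fld, spec$error,
                        seed = derive_seed(spec$base_seed, r, stage = 3L))
      fit_multilevel_poisson(out, z, method = fit_method, nAGQ = nAGQ)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fail[[length(fail) + 1L]] <- data.frame(
        replicate = r, message = conditionMessage(res),
        stringsAsFactors = FALSE
      ) # fits[[r]] stays NULL
    } else {
      fits[[r]] <- res
    }
    if (progress && r %% 50L == 0L) cat(".")
    if (length(fail) > max_fail * spec$n_sims) {
      stop("scenario '", spec$name, "' aborted: ", length(fail),
           " of ", r, " replicates failed (max_fail = ", max_fail, ")")
    }
  }
  if (progress) cat("\n")
  fits <- Filter(Negate(is.null), fits)
  failures <- if (length(fail)) do.call(rbind, fail) else
    data.frame(replicate = integer(), message = character())
  fit_df <- fits_to_df(fits)
  fit_df$replicate <- which(vapply(seq_len(spec$n_sims), function(r)
    !(r %in% failures$replicate), logical(1L)))
  structure(
    list(summary = summarize_performance(fit_df, spec$crf),
         fits = fit_df, spec = spec, failures = failures),
    class = "scenario_result"
  )
}

#' Run a manifest of scenarios and emit results tables
#'
#' Runs each scenario in a manifest (a list of [scenario_spec()] objects, or
#' a YAML file path understood by [read_manifest()]) and binds the
#' performance summaries into one results table with one row per scenario x
#' horizon, mirroring the layout of simulation-study reporting tables
#' (mean estimate, mean SE, percent bias, coverage, power, t-test).
#'
#' @param manifest list of `scenario_spec`s or YAML path.
#' @param out_dir optional output directory: writes `results.csv`,
#'   `fits_<name>.csv` per scenario and `run_log.txt`.
#' @param fit_method,nAGQ,max_fail passed to [run_scenario()].
#' @return object of class `manifest_result`: list with `results`
#'   (data.frame), `scenarios` (list of `scenario_result`), `log` (character).
#' @export
run_manifest <- function(manifest, out_dir = NULL, fit_method = "auto",
                         nAGQ = 1L, max_fail = 0.1) {
  specs <- if (is.character(manifest)) read_manifest(manifest) else manifest
  stopifnot(is.list(specs))
  if (length(specs)) {
    stopifnot(all(vapply(specs, inherits, logical(1L), "scenario_spec")))
    nm <- vapply(specs, `[[`, "", "name")
    if (anyDuplicated(nm)) {
      stop("duplicate scenario names in manifest: ",
           paste(unique(nm[duplicated(nm)]), collapse = ", "))
    }
  }

  header <- c("scenario", "pollutant", "outcome", "pollution_model",
              "site_type", "error_scale", "rho_T", "rho_S", "lambda_T",
              "lambda_S", "horizon", "true_value", "mean_est", "mean_se",
              "pct_bias", "coverage", "power", "t_stat", "t_pvalue",
              "n_effective")
  rows <- list()
  runs <- list()
  log_lines <- character()
  for (sp in specs) {
    t0 <- Sys.time()
    rs <- run_scenario(sp, fit_method = fit_method, nAGQ = nAGQ,
                       max_fail = max_fail)
    runs[[sp$name]] <- rs
    s <- rs$summary
    rows[[sp$name]] <- data.frame(
      scenario = sp$name, pollutant = sp$pollutant, outcome = sp$outcome,
      pollution_model = sp$pollution_model, site_type = sp$site_type,
      error_scale = sp$error$error_scale,
      rho_T = sp$error$rho_T, rho_S = sp$error$rho_S,
      lambda_T = sp$error$lambda_T, lambda_S = sp$error$lambda_S,
      horizon = s$horizon, true_value = s$true_value, mean_est = s$mean_est,
      mean_se = s$mean_se, pct_bias = s$pct_bias, coverage = s$coverage,
      power = s$power, t_stat = s$t_stat, t_pvalue = s$t_pvalue,
      n_effective = s$n_effective, stringsAsFactors = FALSE
    )
    meth <- table(rs$fits$method_used)
    log_lines <- c(log_lines, sprintf(
      "%s: %d/%d replicates ok (%s) in %.1fs",
      sp$name, nrow(rs$fits), sp$n_sims,
      paste(sprintf("%s=%d", names(meth), meth), collapse = ", "),
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ))
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(character(0)), length(header)), header))
  rownames(results) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
    for (nm in names(runs)) {
      write.csv(runs[[nm]]$fits,
                file.path(out_dir, paste0("fits_", nm, ".csv")),
                row.names = FALSE)
    }
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  structure(list(results = results, scenarios = runs, log = log_lines),
            class = "manifest_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> '", x$spec$name, "' (",
      nrow(x$fits), "/", x$spec$n_sims, " replicates)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
print.manifest_result <- function(x, ...) {
  cat("<manifest_result> ", length(x$scenarios), " scenarios, ",
      nrow(x$results), " result rows\n", sep = "")
  invisible(x)
}
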