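#' Read a scenario manifest from YAML
#'
#' The manifest format has two top-level keys: `defaults` (any
#' [scenario_spec()] field, plus nested `error`, `crf`, `truth` parameter
#' maps) and `scenarios`, a list of per-scenario overrides merged onto the
#' defaults. `root_seed` at the top level assigns each scenario
#' `base_seed = root_seed + (i - 1) * 2^20` unless the scenario sets its
#' own, which keeps replicate seeds disjoint across scenarios for up to
#' 2^18 replicates each. A truth map with `scale: log` (or a proportional
#' error map) selects the log-scale pipeline.
#'
#' See `system.file("extdata", "manifest_template.yaml", package =
#' "simexpo")` for a commented template whose error grids span the
#' qualitative regimes of interest (high correlation/low variance ratio
#' through low correlation/high variance ratio).
#'
#' @param path YAML file path.
#' @return list of `scenario_spec` objects.
#' @export
read_manifest <- function(path) {
  doc <- yaml::read_yaml(path)
  defaults <- doc$defaults %||% list()
  scen <- doc$scenarios %||% list()
  root_seed <- doc$root_seed %||% 1L
  lapply(seq_along(scen), function(i) {
    ov <- modifyList(defaults, scen[[i]])
    if (is.null(ov$base_seed)) ov$base_seed <- root_seed + (i - 1L) * 2^20
    spec_from_list(ov)
  })
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a scenario_spec from a plain list (parsed YAML)
#' @keywords internal
spec_from_list <- function(x) {
  err_map <- x$error %||% list()
  crf_map <- x$crf %||% list()
  tr_map <- x$truth %||% list()
  if (identical(err_map$error_scale, "proportional") && is.null(tr_map$scale)) {
    tr_map$scale <- "log"
  }
  truth <- if (identical(tr_map$scale, "log")) {
    do.call(truth_params_log, tr_map[setdiff(names(tr_map), "scale")])
  } else {
    do.call(truth_params, tr_map)
  }
  scenario_spec(
    name = x$name %||% "scenario",
    pollutant = x$pollutant %||% "NO2",
    outcome = x$outcome %||% "all_cause",
    pollution_model = x$pollution_model %||% "custom",
    site_type = x$site_type %||% "background",
    error = do.call(error_params, err_map),
    crf = do.call(crf_set, crf_map),
    truth = truth,
    n_areas = x$n_areas %||% 100,
    n_days = x$n_days %||% 365,
    n_sims = x$n_sims %||% 200,
    base_seed = x$base_seed %||% 1L,
    extent_km = x$extent_km %||% 50,
    population_mean = x$population_mean %||% 1500
  )
}

#' Write a scenario manifest template
#'
#' Copies the packaged YAML template (a small grid of placeholder error
#' parameter combinations spanning the qualitative error regimes) to `path`.
#'
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_manifest_template <- function(path) {
  src <- system.file("extdata", "manifest_template.yaml", package = "simexpo")
  file.copy(src, path, overwrite = TRUE)
  invisible(path)
}
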