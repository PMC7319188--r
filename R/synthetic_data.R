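#' Generate a synthetic small-area geography
#'
#' Creates a set of small areas (census-unit analogues) with planar centroid
#' coordinates and resident populations, to serve as the spatial backbone of
#' a simulation. Centroids are sampled uniformly in a square of side
#' `extent_km`; populations are Poisson around `population_mean`, floored at 1.
#' Coordinates are planar kilometres and all downstream distances Euclidean:
#' the intended study domains (a single conurbation) are small enough that
#' geodesy would add nothing.
#'
#' @param n_areas number of areas (default 1000, a typical city-wide sample
#'   of small census areas).
#' @param extent_km side of the square study domain in km.
#' @param population_mean mean resident count per area (default 1500, the
#'   conventional size of a UK Lower Super Output Area).
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @return an object of class `geography`: a data.frame with columns
#'   `area_id`, `x_km`, `y_km`, `population`.
#' @examples
#' geo <- make_geography(n_areas = 50, seed = 1)
#' mean(geo$population)
#' @export
make_geography <- function(n_areas = 1000, extent_km = 50, population_mean = 1500,
                           seed = 1L) {
  n_areas <- check_count(n_areas, "n_areas", min = 2L)
  check_scalar(extent_km, "extent_km", lower = 0, strict_lower = TRUE)
  check_scalar(population_mean, "population_mean", lower = 1)
  set.seed(seed)
  geo <- data.frame(
    area_id = sprintf("A%04d", seq_len(n_areas)),
    x_km = runif(n_areas, 0, extent_km),
    y_km = runif(n_areas, 0, extent_km),
    population = pmax(1L, rpois(n_areas, population_mean)),
    stringsAsFactors = FALSE
  )
  attr(geo, "extent_km") <- extent_km
  class(geo) <- c("geography", "data.frame")
  geo
}

#' Generate a synthetic monitoring network with latent true daily series
#'
#' Builds a network of fixed monitoring sites of two types (urban/suburban
#' `background` and `roadside` kerbside) scattered uniformly over the study
#' square, and simulates each type's latent *true* daily concentration series
#' from its own spatio-temporal model (see [simulate_truth()]). The stored
#' series are instrument-error-free; [make_validation_pairs()] adds
#' instrument noise when constructing monitor readings.
#'
#' @param n_sites named integer vector giving sites per type, e.g.
#'   `c(background = 47, roadside = 72)` (the defaults mirror a dense urban
#'   NO2 network).
#' @param n_days number of days simulated (default 1826, i.e. five years).
#' @param extent_km side of the square domain in km.
#' @param params named list of [truth_params()] per site type; roadside
#'   defaults are shifted up in mean and spatial spread.
#' @param missing_frac fraction of site-days set missing completely at
#'   random (default 0).
#' @param seed integer seed.
#' @return object of class `monitor_network`: list with `sites` (data.frame
#'   `site_id`, `x_km`, `y_km`, `site_type`), `series` (sites x days matrix of
#'   latent true concentrations, `NA` where missing), `n_days`, `params`.
#' @export
make_monitor_network <- function(n_sites = c(background = 47, roadside = 72),
                                 n_days = 1826, extent_km = 50,
                                 params = NULL, missing_frac = 0, seed = 1L) {
  if (is.null(names(n_sites)) || any(!nzchar(names(n_sites)))) {
    stop("`n_sites` must be a named vector, e.g. c(background = 47, roadside = 72)")
  }
  n_days <- check_count(n_days, "n_days", min = 2L)
  check_scalar(missing_frac, "missing_frac", lower = 0, upper = 1, strict_upper = TRUE)
  if (is.null(params)) {
    params <- list(
      background = truth_params(),
      roadside = truth_params(mu = 55, sigma_S = 7)
    )
  }
  missing_types <- setdiff(names(n_sites), names(params))
  if (length(missing_types)) {
    stop("no truth_params supplied for site type(s): ",
         paste(missing_types, collapse = ", "))
  }

  set.seed(derive_seed(seed, 0L))
  types <- rep(names(n_sites), times = n_sites)
  n_tot <- length(types)
  sites <- data.frame(
    site_id = sprintf("S%03d", seq_len(n_tot)),
    x_km = runif(n_tot, 0, extent_km),
    y_km = runif(n_tot, 0, extent_km),
    site_type = types,
    stringsAsFactors = FALSE
  )

  series <- matrix(NA_real_, n_tot, n_days,
                   dimnames = list(sites$site_id, NULL))
  for (k in seq_along(n_sites)) {
    ty <- names(n_sites)[k]
    idx <- which(sites$site_type == ty)
    if (length(idx) == 0L) next
    geo_ty <- data.frame(
      area_id = sites$site_id[idx],
      x_km = sites$x_km[idx], y_km = sites$y_km[idx],
      population = 1L, stringsAsFactors = FALSE
    )
    class(geo_ty) <- c("geography", "data.frame")
    fld <- simulate_truth(geo_ty, params[[ty]], n_days,
                          seed = derive_seed(seed, k, stage = 2L))
    series[idx, ] <- fld$conc
  }
  if (missing_frac > 0) {
    set.seed(derive_seed(seed, 0L, stage = 3L))
    drop <- runif(length(series)) < missing_frac
    series[drop] <- NA_real_
  }
  structure(
    list(sites = sites, series = series, n_days = n_days, params = params,
         extent_km = extent_km),
    class = "monitor_network"
  )
}

#' Build paired model-monitor validation data with planted error structure
#'
#' Constructs, for each site type in the network, a paired daily dataset of
#' monitor readings and pseudo-model predictions with *known* error
#' parameters, for testing the validation-side estimator. Monitor readings
#' are the latent true series plus iid Gaussian instrument noise with sd
#' `instrument_sd`; model predictions are generated from the latent true
#' series by the same correlation/variance-ratio injection rule as
#' [inject_error()], so the latent (rho_T, rho_S, lambda_T, lambda_S)
#' equal the planted values.
#'
#' For proportional (`error_scale = "proportional"`) planted parameters the
#' network series must be on the log scale (see [truth_params()]); instrument
#' noise is then additive on the log scale (multiplicative in concentration)
#' and both stored series are returned on the natural scale.
#'
#' @param network a [make_monitor_network()] object.
#' @param planted an [error_params()] object: the error structure to plant.
#' @param instrument_sd instrument noise sd (concentration units, or log
#'   units under proportional error); scalar or one value per site.
#' @param seed integer seed.
#' @return object of class `validation_pairs`: list with `pairs` (data.frame
#'   `site_id`, `site_type`, `day`, `monitor`, `model`; complete cases only),
#'   `instrument_error_variance` (named per-site vector), `scale`.
#' @export
make_validation_pairs <- function(network, planted = error_params(),
                                  instrument_sd = 0, seed = 1L) {
  stopifnot(inherits(network, "monitor_network"))
  stopifnot(inherits(planted, "error_params"))
  if (any(instrument_sd < 0)) stop("`instrument_sd` must be >= 0")
  n_site <- nrow(network$sites)
  inst_sd <- rep_len(instrument_sd, n_site)
  names(inst_sd) <- network$sites$site_id

  proportional <- planted$error_scale == "proportional"
  if (proportional) {
    scales <- vapply(network$params, function(p) p$scale, "")
    if (any(scales != "log")) {
      stop("proportional planted error requires a log-scale monitor network ",
           "(truth_params(scale = 'log'))")
    }
  }

  model <- matrix(NA_real_, n_site, network$n_days,
                  dimnames = dimnames(network$series))
  for (k in seq_along(unique(network$sites$site_type))) {
    ty <- unique(network$sites$site_type)[k]
    idx <- which(network$sites$site_type == ty)
    if (length(idx) < 2L) {
      stop("site type '", ty, "' has fewer than 2 sites: spatial error ",
           "components are undefined")
    }
    lat <- network$series[idx, , drop = FALSE]
    fld <- structure(
      list(conc = lat, geography = NULL, n_days = network$n_days,
           scale = if (proportional) "log" else "natural"),
      class = "truth_field"
    )
    z <- inject_error(fld, planted, seed = derive_seed(seed, k, stage = 0L))
    model[idx, ] <- z$conc
  }

  set.seed(derive_seed(seed, 0L, stage = 1L))
  noise <- matrix(rnorm(length(network$series)), n_site) * inst_sd
  monitor <- network$series + noise

  if (proportional) {
    monitor <- exp(monitor)
    model <- exp(model)
  }

  df <- data.frame(
    site_id = rep(network$sites$site_id, times = network$n_days),
    site_type = rep(network$sites$site_type, times = network$n_days),
    day = rep(seq_len(network$n_days), each = n_site),
    monitor = as.vector(monitor),
    model = as.vector(model),
    stringsAsFactors = FALSE
  )
  df <- df[stats::complete.cases(df), , drop = FALSE]
  rownames(df) <- NULL
  structure(
    list(pairs = df, instrument_error_variance = inst_sd^2,
         scale = if (proportional) "proportional" else "additive",
         planted = planted),
    class = "validation_pairs"
  )
}

#' Write a geography to CSV
#'
#' @param geography a [make_geography()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geography_csv <- function(geography, path) {
  stopifnot(inherits(geography, "geography"))
  write.csv(as.data.frame(geography), path, row.names = FALSE)
  invisible(path)
}

#' Write paired model-monitor series to long-format CSV
#'
#' Columns: `site_id`, `site_type`, `day`, `monitor`, `model`.
#'
#' @param pairs a [make_validation_pairs()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pairs_csv <- function(pairs, path) {
  stopifnot(inherits(pairs, "validation_pairs"))
  write.csv(pairs$pairs, path, row.names = FALSE)
  invisible(path)
}

#' Read paired model-monitor series from long-format CSV
#'
#' Expects the column layout of [write_pairs_csv()]. Incomplete records are
#' dropped. `instrument_error_variance` must be supplied by the user (it is a
#' property of the monitoring equipment, not of the file).
#'
#' @param path CSV path with columns `site_id`, `site_type`, `day`,
#'   `monitor`, `model`.
#' @param instrument_error_variance scalar or per-site named vector of
#'   instrument noise variance; default 0 (no correction).
#' @param scale `"additive"` or `"proportional"` (controls downstream
#'   analysis scale).
#' @return a `validation_pairs` object.
#' @export
read_pairs_csv <- function(path, instrument_error_variance = 0,
                           scale = c("additive", "proportional")) {
  scale <- match.arg(scale)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "site_type", "day", "monitor", "model")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[stats::complete.cases(df[, need]), need]
  ids <- unique(df$site_id)
  if (is.null(names(instrument_error_variance))) {
    iev <- setNames(rep_len(instrument_error_variance, length(ids)), ids)
  } else {
    missing_ids <- setdiff(ids, names(instrument_error_variance))
    if (length(missing_ids)) {
      stop("instrument_error_variance missing for sites: ",
           paste(missing_ids, collapse = ", "))
    }
    iev <- instrument_error_variance[ids]
  }
  if (any(iev < 0)) stop("instrument_error_variance must be >= 0")
  structure(
    list(pairs = df, instrument_error_variance = iev, scale = scale,
         planted = NULL),
    class = "validation_pairs"
  )
}

#' @export
print.monitor_network <- function(x, ...) {
  tab <- table(x$sites$site_type)
  cat("<monitor_network> ", nrow(x$sites), " sites (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      "), ", x$n_days, " days\n", sep = "")
  invisible(x)
}

#' @export
print.validation_pairs <- function(x, ...) {
  cat("<validation_pairs> ", nrow(x$pairs), " paired records, ",
      length(unique(x$pairs$site_id)), " sites, scale: ", x$scale, "\n",
      sep = "")
  invisible(x)
}
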