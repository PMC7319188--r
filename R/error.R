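#' Error-structure parameters for pseudo-modeled exposure (Step 3 knobs)
#'
#' Parameterizes the relationship between pseudo-modeled and true exposure
#' through four quantities, computed separately for the spatial (between-area
#' period means) and temporal (within-area daily deviations) components:
#' the Pearson correlation (`rho_S`, `rho_T`) and the variance ratio
#' model/true (`lambda_S`, `lambda_T`). `error_scale = "additive"` injects
#' error on the concentration scale; `"proportional"` on the log scale
#' (multiplicative error), in which case the whole pipeline runs on log
#' concentrations and back-transforms at the outcome/fitting boundary.
#'
#' Classical additive error (model = truth + independent noise) corresponds
#' to `lambda > 1` with `rho = 1/sqrt(lambda)`; Berkson error (truth = model
#' + independent noise) to `lambda < 1` with `rho = sqrt(lambda)`. See
#' [classical_error_params()] and [berkson_error_params()].
#'
#' @param rho_T,rho_S temporal and spatial correlations, in `[-1, 1]`.
#' @param lambda_T,lambda_S temporal and spatial variance ratios, > 0.
#' @param error_scale `"additive"` or `"proportional"`.
#' @param pollutant,pollution_model,site_type free-text scenario labels
#'   (`pollution_model` conventionally one of LUR, dispersion, hybrid1,
#'   hybrid2, custom).
#' @return object of class `error_params`.
#' @examples
#' error_params()                       # identity (error-free) structure
#' classical_error_params(1)            # classical noise, var equal to signal
#' @export
error_params <- function(rho_T = 1, rho_S = 1, lambda_T = 1, lambda_S = 1,
                         error_scale = c("additive", "proportional"),
                         pollutant = "NO2", pollution_model = "custom",
                         site_type = "background") {
  error_scale <- match.arg(error_scale)
  check_scalar(rho_T, "rho_T", lower = -1, upper = 1)
  check_scalar(rho_S, "rho_S", lower = -1, upper = 1)
  check_scalar(lambda_T, "lambda_T", lower = 0, strict_lower = TRUE)
  check_scalar(lambda_S, "lambda_S", lower = 0, strict_lower = TRUE)
  structure(
    list(rho_T = rho_T, rho_S = rho_S, lambda_T = lambda_T,
         lambda_S = lambda_S, error_scale = error_scale,
         pollutant = pollutant, pollution_model = pollution_model,
         site_type = site_type),
    class = "error_params"
  )
}

#' Error parameters equivalent to classical additive noise
#'
#' Classical error adds independent noise U to the truth: Z = X + U with
#' noise-to-signal variance ratio \eqn{\kappa = \sigma_U^2/\sigma_X^2}.
#' Its second-moment encoding is \eqn{\lambda = 1 + \kappa},
#' \eqn{\rho = 1/\sqrt{1+\kappa}} (so \eqn{\rho = 1/\sqrt{\lambda}}).
#'
#' @param kappa_S,kappa_T spatial and temporal noise/signal variance ratios
#'   (>= 0).
#' @param ... passed to [error_params()] (labels, error_scale).
#' @return an `error_params` object.
#' @export
classical_error_params <- function(kappa_S = 0, kappa_T = 0, ...) {
  check_scalar(kappa_S, "kappa_S", lower = 0)
  check_scalar(kappa_T, "kappa_T", lower = 0)
  error_params(rho_S = 1 / sqrt(1 + kappa_S), lambda_S = 1 + kappa_S,
               rho_T = 1 / sqrt(1 + kappa_T), lambda_T = 1 + kappa_T, ...)
}

#' Error parameters equivalent to Berkson noise
#'
#' Berkson error makes the truth equal the model plus independent noise:
#' X = Z + V. The model then has smaller variance than the truth
#' (\eqn{\lambda < 1}) and \eqn{\rho = \sqrt{\lambda}}. Effect estimates stay
#' (first-order) unbiased but standard errors inflate.
#'
#' @param lambda_S,lambda_T spatial and temporal variance ratios in `(0, 1]`.
#' @param ... passed to [error_params()].
#' @return an `error_params` object.
#' @export
berkson_error_params <- function(lambda_S = 1, lambda_T = 1, ...) {
  check_scalar(lambda_S, "lambda_S", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(lambda_T, "lambda_T", lower = 0, upper = 1, strict_lower = TRUE)
  error_params(rho_S = sqrt(lambda_S), lambda_S = lambda_S,
               rho_T = sqrt(lambda_T), lambda_T = lambda_T, ...)
}

#' Inject measurement error into a true field (Step 3)
#'
#' Generates a pseudo-modeled field Z from the truth X so that, in
#' expectation, the correlation and variance ratio between Z and X equal the
#' prespecified values, separately for the spatial and temporal components.
#' With the truth decomposed as \eqn{X_{it} = \bar X_i + D_{it}},
#' \eqn{m = \mathrm{mean}_i(\bar X_i)}, \eqn{\sigma_S^2 =
#' \mathrm{var}_i(\bar X_i)} and \eqn{\sigma_T^2 = \mathrm{var}(D_{it})}
#' (sample moments of the realized field, so the variance-ratio calibration
#' refers to the data actually used):
#' \deqn{\bar Z_i = m + \rho_S \sqrt{\lambda_S} (\bar X_i - m) +
#'       \sqrt{\lambda_S \sigma_S^2 (1 - \rho_S^2)}\, \eta_i}
#' \deqn{E_{it} = \rho_T \sqrt{\lambda_T} D_{it} +
#'       \sqrt{\lambda_T \sigma_T^2 (1 - \rho_T^2)}\, \nu_{it}}
#' with \eqn{\eta_i, \nu_{it}} iid standard normal, and
#' \eqn{Z_{it} = \bar Z_i + E_{it} + } `mean_offset`. Injection noise is
#' independent across areas and days (no spatially correlated model error).
#' The overall mean is preserved in expectation; identity parameters
#' reproduce the truth exactly.
#'
#' Proportional error requires a log-scale field (the injection then acts on
#' log concentrations); additive error requires a natural-scale field. The
#' returned field keeps the input scale — use [as_natural()] (done
#' automatically by [simulate_outcomes()] and [fit_multilevel_poisson()])
#' to back-transform.
#'
#' @param field a `truth_field`.
#' @param err an [error_params()] object.
#' @param seed integer seed.
#' @param mean_offset optional additive mean shift of the pseudo-model
#'   (default 0; mean shifts do not bias log-linear slope estimates but are
#'   available for sensitivity runs).
#' @return a `truth_field` (pseudo-modeled) with attribute `pseudo = TRUE`
#'   and the `error_params` stored as attribute `error`.
#' @export
inject_error <- function(field, err, seed = 1L, mean_offset = 0) {
  stopifnot(inherits(field, "truth_field"), inherits(err, "error_params"))
  check_scalar(mean_offset, "mean_offset")
  if (err$error_scale == "proportional" && !identical(field$scale, "log")) {
    stop("proportional error requires a log-scale field ",
         "(simulate the truth with truth_params(scale = 'log'))")
  }
  if (err$error_scale == "additive" && !identical(field$scale, "natural")) {
    stop("additive error requires a natural-scale field")
  }
  # NA-aware decomposition: missing days (monitor series) stay missing in the
  # pseudo-model and are dropped downstream; truth fields are complete.
  x <- field$conc
  xbar <- rowMeans(x, na.rm = TRUE)
  D <- x - xbar
  n <- length(xbar)
  m <- mean(xbar)
  s2_S <- var(xbar)
  s2_T <- var(as.vector(D), na.rm = TRUE)

  set.seed(seed)
  eta <- rnorm(n)
  nu <- matrix(rnorm(length(D)), n)
  zbar <- m + err$rho_S * sqrt(err$lambda_S) * (xbar - m) +
    sqrt(err$lambda_S * s2_S * (1 - err$rho_S^2)) * eta
  E <- err$rho_T * sqrt(err$lambda_T) * D +
    sqrt(err$lambda_T * s2_T * (1 - err$rho_T^2)) * nu

  out <- field
  out$conc <- zbar + E + mean_offset
  dimnames(out$conc) <- dimnames(field$conc)
  attr(out, "pseudo") <- TRUE
  attr(out, "error") <- err
  out
}

#' Inject classical additive noise directly
#'
#' The direct construction Z = X + U with independent spatial (per-area) and
#' temporal (per-area-day) noise components, used as an independent check of
#' the (rho, lambda) encoding of classical error: adding spatial noise with
#' sd `noise_sd_S` and temporal noise with sd `noise_sd_T` reproduces the
#' second moments of [inject_error()] with
#' [classical_error_params()]`(kappa_S, kappa_T)` where
#' `kappa = noise_sd^2 / component variance`.
#'
#' @param field a `truth_field` on the natural scale.
#' @param noise_sd_S sd of per-area (spatial) noise.
#' @param noise_sd_T sd of per-area-day (temporal) noise.
#' @param seed integer seed.
#' @return a pseudo-modeled `truth_field`.
#' @export
inject_classical <- function(field, noise_sd_S = 0, noise_sd_T = 0, seed = 1L) {
  stopifnot(inherits(field, "truth_field"))
  check_scalar(noise_sd_S, "noise_sd_S", lower = 0)
  check_scalar(noise_sd_T, "noise_sd_T", lower = 0)
  set.seed(seed)
  n <- nrow(field$conc)
  u_s <- rnorm(n, 0, noise_sd_S)
  u_t <- matrix(rnorm(length(field$conc), 0, noise_sd_T), n)
  out <- field
  out$conc <- field$conc + u_s + u_t
  attr(out, "pseudo") <- TRUE
  out
}

#' @export
print.error_params <- function(x, ...) {
  cat("<error_params> rho_T=", x$rho_T, " rho_S=", x$rho_S,
      " lambda_T=", x$lambda_T, " lambda_S=", x$lambda_S,
      " scale=", x$error_scale, " [", x$pollutant, "/", x$pollution_model,
      "/", x$site_type, "]\n", sep = "")
  invisible(x)
}
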