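#' Summarize replicate fits into performance measures
#'
#' Aggregates a set of per-replicate [fit_multilevel_poisson()] results into
#' the usual Monte Carlo performance measures for each exposure horizon
#' (short-term, long-term): average estimate, average standard error,
#' percent bias relative to the true coefficient, coverage probability of
#' nominal 95% Wald intervals, power of the two-sided 5% test, and a
#' one-sample t-test of the replicate estimates against the truth (a check
#' that residual bias is not an artifact of Monte Carlo noise).
#'
#' All comparisons are on the reporting scale (per 10 ug/m3): the target for
#' a horizon with true per-unit CRF beta is `10 * beta`. When the true
#' coefficient is zero, percent bias is undefined; the row is flagged
#' (`bias_flag = "absolute"`) and `pct_bias` set to `NA` while `abs_bias`
#' always carries `mean_est - 10 * beta`. Non-converged replicates are
#' excluded and counted in `n_excluded`.
#'
#' @param fits list of `fit_result` objects (or a data.frame with columns
#'   `est_ST`, `se_ST`, `est_LT`, `se_LT`, `converged`).
#' @param truth the generating [crf_set()].
#' @param report_per reporting scale used by the fits (default 10).
#' @return a `performance_summary`: data.frame with one row per horizon and
#'   columns `horizon`, `true_value`, `mean_est`, `mean_se`, `pct_bias`,
#'   `abs_bias`, `bias_flag`, `coverage`, `power`, `t_stat`, `t_pvalue`,
#'   `n_effective`; attributes `n_sims`, `n_excluded`. Coverage and power in
#'   percent.
#' @export
summarize_performance <- function(fits, truth, report_per = 10) {
  stopifnot(inherits(truth, "crf_set"))
  df <- if (is.data.frame(fits)) fits else fits_to_df(fits)
  n_sims <- nrow(df)
  keep <- df[is.finite(df$est_ST) & is.finite(df$est_LT) & df$converged, ,
             drop = FALSE]
  if (nrow(keep) < 2L) stop("need at least 2 converged fits to summarize")

  one <- function(est, se, beta) {
    target <- report_per * beta
    mean_est <- mean(est)
    z <- qnorm(0.975)
    cover <- 100 * mean(est - z * se <= target & target <= est + z * se)
    power <- 100 * mean(abs(est / se) > z)
    tt <- if (sd(est) > 0) t.test(est, mu = target) else
      list(statistic = c(t = NaN), p.value = NaN) # degenerate: no MC spread
    data.frame(
      true_value = target,
      mean_est = mean_est,
      mean_se = mean(se),
      pct_bias = if (beta != 0) 100 * (mean_est - target) / target else NA_real_,
      abs_bias = mean_est - target,
      bias_flag = if (beta != 0) "percent" else "absolute",
      coverage = cover,
      power = power,
      t_stat = unname(tt$statistic),
      t_pvalue = tt$p.value,
      n_effective = nrow(keep),
      stringsAsFactors = FALSE
    )
  }

  out <- rbind(
    cbind(horizon = "ST", one(keep$est_ST, keep$se_ST, truth$beta_ST)),
    cbind(horizon = "LT", one(keep$est_LT, keep$se_LT, truth$beta_LT))
  )
  rownames(out) <- NULL
  attr(out, "n_sims") <- n_sims
  attr(out, "n_excluded") <- n_sims - nrow(keep)
  class(out) <- c("performance_summary", "data.frame")
  out
}

#' Collect fit results into a data.frame
#'
#' @param fits list of `fit_result` objects.
#' @return data.frame with one row per fit.
#' @export
fits_to_df <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  do.call(rbind, lapply(fits, function(f) {
    data.frame(est_ST = f$est_ST, se_ST = f$se_ST, est_LT = f$est_LT,
               se_LT = f$se_LT, sigma_u_hat = f$sigma_u_hat,
               converged = isTRUE(f$converged),
               method_used = as.character(f$method_used),
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.performance_summary <- function(x, digits = 4, ...) {
  cat("<performance_summary> ", attr(x, "n_sims"), " replicates (",
      attr(x, "n_excluded"), " excluded)\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
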