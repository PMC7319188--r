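#' Estimate error parameters from paired model-monitor validation data
#'
#' Computes the temporal and spatial correlation coefficients and variance
#' ratios (model versus true) from paired daily model predictions and
#' monitor measurements, with a moment correction for instrument error in
#' the monitor readings so the estimates reflect modeled-versus-*true*
#' rather than modeled-versus-monitored comparisons.
#'
#' Both series are decomposed into site period means (spatial component) and
#' per-site-centred daily deviations (temporal component, pooled across
#' sites of the type). Writing \eqn{v_O} for the monitor deviation variance,
#' \eqn{v_M} for the model deviation variance, \eqn{r} for their Pearson
#' correlation and \eqn{v_I} for the (pooled) instrument noise variance, the
#' naive estimates are \eqn{\hat\lambda_T = v_M/v_O}, \eqn{\hat\rho_T = r};
#' the corrected ones use the disattenuation
#' \deqn{\lambda_T = v_M/(v_O - v_I), \qquad
#'       \rho_T = r \sqrt{v_O/(v_O - v_I)}.}
#' The model side needs no correction (model output carries no instrument
#' noise). The same algebra applies to the spatial component computed on
#' site means, with the instrument variance divided by each site's number of
#' observation days (iid noise averages out in the mean), which makes the
#' spatial correction negligible for multi-year series. Under
#' `scale = "proportional"` the identical algebra is applied to
#' log-transformed series, with `instrument_error_variance` interpreted on
#' the log scale.
#'
#' A corrected correlation can exceed 1 by sampling noise when the model is
#' essentially the noise-free truth; it is then capped at +/-1 and the
#' uncapped value kept in `naive`/`raw` bookkeeping.
#'
#' @param pairs a `validation_pairs` object ([make_validation_pairs()] or
#'   [read_pairs_csv()]).
#' @param site_type which site type to analyse; `NULL` (default) pools all.
#' @param scale `"additive"` (concentration scale) or `"proportional"`
#'   (log scale); defaults to the pairs' own scale.
#' @param correct apply the instrument-error correction (default TRUE).
#' @param pooled pool temporal deviations across sites after per-site
#'   centering (default, maximizes stability); `FALSE` computes per-site
#'   temporal estimates and averages them across sites.
#' @return object of class `error_param_estimate`: list with `params` (an
#'   [error_params()] with the corrected — or, if `correct = FALSE`, naive —
#'   estimates), `naive` (uncorrected rho/lambda), `raw` (uncapped corrected
#'   values), `n_sites`, `n_obs`, `capped`.
#' @export
estimate_error_params <- function(pairs, site_type = NULL,
                                  scale = NULL, correct = TRUE,
                                  pooled = TRUE) {
  stopifnot(inherits(pairs, "validation_pairs"))
  if (is.null(scale)) scale <- pairs$scale
  scale <- match.arg(scale, c("additive", "proportional"))
  df <- pairs$pairs
  if (!is.null(site_type)) df <- df[df$site_type %in% site_type, , drop = FALSE]
  if (nrow(df) == 0L) stop("no records for site_type ", site_type)

  if (scale == "proportional") {
    if (any(df$monitor <= 0) || any(df$model <= 0)) {
      stop("proportional scale requires strictly positive concentrations")
    }
    df$monitor <- log(df$monitor)
    df$model <- log(df$model)
  }

  sites <- unique(df$site_id)
  if (length(sites) < 3L) {
    stop("need >= 3 sites for spatial error components (got ",
         length(sites), ")")
  }
  days_per_site <- table(df$site_id)[sites]
  if (any(days_per_site < 2L)) {
    stop("every site needs >= 2 paired days")
  }
  iev <- pairs$instrument_error_variance
  iev <- iev[match(sites, names(iev))]
  if (anyNA(iev)) iev <- rep_len(pairs$instrument_error_variance[1L], length(sites))
  names(iev) <- sites

  # spatial component: site means
  O_s <- tapply(df$monitor, factor(df$site_id, levels = sites), mean)
  M_s <- tapply(df$model, factor(df$site_id, levels = sites), mean)
  v_O_S <- var(O_s)
  v_M_S <- var(M_s)
  r_S <- cor(O_s, M_s)
  v_I_S <- mean(iev / as.numeric(days_per_site)) # noise averaged over days

  # temporal component: per-site centred deviations
  ctr_O <- df$monitor - O_s[df$site_id]
  ctr_M <- df$model - M_s[df$site_id]
  if (pooled) {
    # pooled variances with per-site centering lose one df per site
    dfree <- nrow(df) - length(sites)
    v_O_T <- sum(ctr_O^2) / dfree
    v_M_T <- sum(ctr_M^2) / dfree
    r_T <- sum(ctr_O * ctr_M) / sqrt(sum(ctr_O^2) * sum(ctr_M^2))
    w <- (as.numeric(days_per_site) - 1L)
    v_I_T <- sum(w * iev) / sum(w)
  } else {
    per <- vapply(sites, function(s) {
      o <- ctr_O[df$site_id == s]; m <- ctr_M[df$site_id == s]
      c(var(o), var(m), cor(o, m))
    }, numeric(3L))
    v_O_T <- mean(per[1L, ]); v_M_T <- mean(per[2L, ]); r_T <- mean(per[3L, ])
    v_I_T <- mean(iev)
  }

  naive <- list(rho_T = r_T, rho_S = r_S,
                lambda_T = v_M_T / v_O_T, lambda_S = v_M_S / v_O_S)

  if (correct) {
    true_T <- v_O_T - v_I_T
    true_S <- v_O_S - v_I_S
    if (true_T <= 0 || true_S <= 0) {
      stop("instrument variance exceeds observed variance (",
           if (true_T <= 0) "temporal" else "spatial",
           " component); check instrument_error_variance")
    }
    raw <- list(
      rho_T = r_T * sqrt(v_O_T / true_T),
      rho_S = r_S * sqrt(v_O_S / true_S),
      lambda_T = v_M_T / true_T,
      lambda_S = v_M_S / true_S
    )
  } else {
    raw <- naive
  }
  capped <- abs(c(raw$rho_T, raw$rho_S)) > 1
  est <- raw
  est$rho_T <- max(-1, min(1, est$rho_T))
  est$rho_S <- max(-1, min(1, est$rho_S))

  structure(
    list(
      params = error_params(
        rho_T = est$rho_T, rho_S = est$rho_S,
        lambda_T = est$lambda_T, lambda_S = est$lambda_S,
        error_scale = if (scale == "proportional") "proportional" else "additive",
        site_type = if (is.null(site_type)) "all" else paste(site_type, collapse = "+")
      ),
      naive = naive, raw = raw,
      n_sites = length(sites), n_obs = nrow(df),
      capped = any(capped), corrected = correct
    ),
    class = "error_param_estimate"
  )
}

#' Standard air-quality model validation metrics
#'
#' Computes, per monitoring site and as unweighted site-type averages, the
#' standard model-evaluation statistics over paired days with model value M
#' and monitor value O:
#' mean bias `MB = mean(M - O)`; normalized mean bias
#' `NMB = sum(M - O)/sum(O)`; normalized mean gross error
#' `NMGE = sum(|M - O|)/sum(O)`; root mean squared error
#' `RMSE = sqrt(mean((M - O)^2))`; and `FAC2`, the fraction of days with
#' `0.5 <= M/O <= 2` (closed interval). Days with `O <= 0` are excluded from
#' FAC2 and the normalized metrics, with the exclusion count reported; a
#' site whose monitor values are all `<= 0` gets `NA` normalized metrics and
#' is flagged.
#'
#' @param pairs a `validation_pairs` object.
#' @return object of class `validation_stats`: list with `per_site`
#'   (data.frame: `site_id`, `site_type`, `n_days`, `MB`, `NMB`, `NMGE`,
#'   `RMSE`, `FAC2`), `by_type` (unweighted means over sites per type),
#'   `n_excluded_nonpositive`.
#' @export
standard_metrics <- function(pairs) {
  stopifnot(inherits(pairs, "validation_pairs"))
  df <- pairs$pairs
  sites <- unique(df$site_id)
  excl <- 0L
  per <- do.call(rbind, lapply(sites, function(s) {
    d <- df[df$site_id == s, , drop = FALSE]
    M <- d$model; O <- d$monitor
    diff <- M - O
    pos <- O > 0
    excl <<- excl + sum(!pos)
    data.frame(
      site_id = s,
      site_type = d$site_type[1L],
      n_days = nrow(d),
      MB = mean(diff),
      NMB = if (any(pos)) sum(diff[pos]) / sum(O[pos]) else NA_real_,
      NMGE = if (any(pos)) sum(abs(diff[pos])) / sum(O[pos]) else NA_real_,
      RMSE = sqrt(mean(diff^2)),
      FAC2 = if (any(pos)) mean(M[pos] / O[pos] >= 0.5 & M[pos] / O[pos] <= 2)
             else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(per) <- NULL
  by_type <- do.call(rbind, lapply(split(per, per$site_type), function(g) {
    data.frame(
      site_type = g$site_type[1L], n_sites = nrow(g),
      MB = mean(g$MB), NMB = mean(g$NMB), NMGE = mean(g$NMGE),
      RMSE = mean(g$RMSE), FAC2 = mean(g$FAC2), stringsAsFactors = FALSE
    )
  }))
  rownames(by_type) <- NULL
  structure(
    list(per_site = per, by_type = by_type, n_excluded_nonpositive = excl),
    class = "validation_stats"
  )
}

#' Leave-out partition of monitoring sites
#'
#' Splits the network's sites into successive disjoint groups of roughly
#' `fraction` of the sites each, covering every site exactly once — the
#' bookkeeping behind leave-10%-out validation of exposure models that use
#' monitor data in training.
#'
#' @param network a `monitor_network` (or a character vector of site ids).
#' @param fraction left-out fraction per group, in (0, 1); default 0.1.
#' @param seed integer seed (groups are a random partition).
#' @return list of character vectors of site ids: pairwise disjoint, union =
#'   all sites, sizes differing by at most 1.
#' @export
leave_out_split <- function(network, fraction = 0.1, seed = 1L) {
  ids <- if (inherits(network, "monitor_network")) network$sites$site_id
         else as.character(network)
  check_scalar(fraction, "fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  n <- length(ids)
  n_groups <- ceiling(1 / fraction - 1e-9)
  if (floor(n / n_groups) < 1L) {
    stop("fraction ", fraction, " yields empty groups for ", n, " sites")
  }
  set.seed(seed)
  shuffled <- sample(ids)
  grp <- rep(seq_len(n_groups), length.out = n) # sizes differ by <= 1
  grp <- sort(grp)
  unname(split(shuffled, grp))
}

#' @export
print.error_param_estimate <- function(x, ...) {
  cat("<error_param_estimate> ", x$n_sites, " sites, ", x$n_obs, " records",
      if (!x$corrected) " (naive, uncorrected)",
      if (x$capped) " [correlation capped at 1]", "\n", sep = "")
  print(x$params)
  cat(sprintf("  naive: rho_T=%.3f rho_S=%.3f lambda_T=%.3f lambda_S=%.3f\n",
              x$naive$rho_T, x$naive$rho_S, x$naive$lambda_T, x$naive$lambda_S))
  invisible(x)
}

#' @export
print.validation_stats <- function(x, ...) {
  cat("<validation_stats> ", nrow(x$per_site), " sites; site-type averages:\n",
      sep = "")
  print.data.frame(x$by_type, digits = 3, row.names = FALSE)
  invisible(x)
}
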