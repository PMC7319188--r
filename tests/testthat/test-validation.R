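test_that("identity pairs give (1, 1, 1, 1) and corrections are no-ops at zero instrument variance", {
  set.seed(1)
  n_site <- 6; n_day <- 40
  mu_s <- rnorm(n_site, 40, 5)
  vals <- mu_s + matrix(rnorm(n_site * n_day, 0, 8), n_site)
  vp <- pairs_fixture(
    site_id = rep(sprintf("S%02d", 1:n_site), each = n_day),
    site_type = "background",
    day = rep(1:n_day, times = n_site),
    monitor = as.vector(t(vals)), model = as.vector(t(vals))
  )
  e <- estimate_error_params(vp)
  expect_equal(e$params$rho_T, 1, tolerance = 1e-12)
  expect_equal(e$params$rho_S, 1, tolerance = 1e-12)
  expect_equal(e$params$lambda_T, 1, tolerance = 1e-12)
  expect_equal(e$params$lambda_S, 1, tolerance = 1e-12)
  # zero instrument variance: corrected equals naive
  expect_equal(unlist(e$raw), unlist(e$naive), tolerance = 1e-12)
})

test_that("standard metrics match the hand-computed example", {
  vp <- pairs_fixture(
    site_id = rep("S01", 4), site_type = "roadside", day = 1:4,
    monitor = c(10, 10, 10, 10), model = c(5, 10, 20, 45)
  )
  m <- standard_metrics(vp)$per_site
  expect_equal(m$MB, 10)           # mean(c(-5, 0, 10, 35))
  expect_equal(m$NMB, 1.0)         # 40/40
  expect_equal(m$NMGE, 1.25)       # 50/40
  expect_equal(m$RMSE, sqrt(mean(c(25, 0, 100, 1225))))
  expect_equal(m$FAC2, 3 / 4)      # 0.5 and 2.0 are inside the closed interval
})

test_that("metrics equal brute-force recomputation on a randomized 10-site fixture", {
  set.seed(7)
  n_day <- 30
  ids <- sprintf("S%02d", 1:10)
  df <- do.call(rbind, lapply(ids, function(s) {
    o <- runif(n_day, 5, 80)
    data.frame(site_id = s,
               site_type = if (s < "S06") "background" else "roadside",
               day = 1:n_day, monitor = o,
               model = o * runif(n_day, 0.3, 2.5),
               stringsAsFactors = FALSE)
  }))
  vp <- pairs_fixture(df$site_id, df$site_type, df$day, df$monitor, df$model)
  got <- standard_metrics(vp)

  for (s in ids) {
    d <- df[df$site_id == s, ]
    mb <- 0; se2 <- 0; num <- 0; anum <- 0; den <- 0; f2 <- 0
    for (k in seq_len(nrow(d))) {
      mb <- mb + (d$model[k] - d$monitor[k]) / nrow(d)
      se2 <- se2 + (d$model[k] - d$monitor[k])^2 / nrow(d)
      num <- num + (d$model[k] - d$monitor[k])
      anum <- anum + abs(d$model[k] - d$monitor[k])
      den <- den + d$monitor[k]
      r <- d$model[k] / d$monitor[k]
      if (r >= 0.5 && r <= 2) f2 <- f2 + 1 / nrow(d)
    }
    row <- got$per_site[got$per_site$site_id == s, ]
    expect_equal(row$MB, mb)
    expect_equal(row$RMSE, sqrt(se2))
    expect_equal(row$NMB, num / den)
    expect_equal(row$NMGE, anum / den)
    expect_equal(row$FAC2, f2)
  }
  # site-type averages are unweighted means over sites
  bg <- got$per_site[got$per_site$site_type == "background", ]
  expect_equal(got$by_type$FAC2[got$by_type$site_type == "background"],
               mean(bg$FAC2))
})

test_that("non-positive monitor days are excluded from normalized metrics and flagged", {
  vp <- pairs_fixture(
    site_id = rep("S01", 3), site_type = "background", day = 1:3,
    monitor = c(0, 10, 20), model = c(5, 12, 18)
  )
  m <- standard_metrics(vp)
  expect_equal(m$n_excluded_nonpositive, 1L)
  expect_equal(m$per_site$NMB, (2 - 2) / 30)
  expect_equal(m$per_site$MB, mean(c(5, 2, -2))) # MB keeps all days
  # all-nonpositive site: normalized metrics undefined
  vp2 <- pairs_fixture(rep("S01", 2), "background", 1:2,
                       monitor = c(0, -1), model = c(1, 1))
  m2 <- standard_metrics(vp2)
  expect_true(is.na(m2$per_site$NMB) && is.na(m2$per_site$FAC2))
})

test_that("estimates are invariant to shifts and affine rescaling", {
  net <- make_monitor_network(c(background = 12), n_days = 150, seed = 3)
  vp <- make_validation_pairs(
    net, error_params(rho_T = 0.7, rho_S = 0.8, lambda_T = 1.4, lambda_S = 1.3),
    instrument_sd = 0, seed = 4
  )
  e0 <- estimate_error_params(vp)
  shift <- vp
  shift$pairs$monitor <- shift$pairs$monitor + 100
  shift$pairs$model <- shift$pairs$model + 100
  e1 <- estimate_error_params(shift)
  expect_equal(e1$params$lambda_T, e0$params$lambda_T, tolerance = 1e-10)
  expect_equal(e1$params$lambda_S, e0$params$lambda_S, tolerance = 1e-10)
  expect_equal(e1$params$rho_T, e0$params$rho_T, tolerance = 1e-10)

  scaled <- vp
  scaled$pairs$model <- 2.5 * scaled$pairs$model + 7
  e2 <- estimate_error_params(scaled)
  expect_equal(e2$params$rho_T, e0$params$rho_T, tolerance = 1e-10)
  expect_equal(e2$params$rho_S, e0$params$rho_S, tolerance = 1e-10)
  expect_equal(e2$params$lambda_T, 2.5^2 * e0$params$lambda_T, tolerance = 1e-8)
})

test_that("instrument correction removes attenuation when the model is the truth", {
  set.seed(5)
  n_site <- 25; n_day <- 600; inst_sd <- 6
  mu_s <- rnorm(n_site, 40, 5)
  true <- mu_s + matrix(rnorm(n_site * n_day, 0, 9), n_site)
  monitor <- true + matrix(rnorm(n_site * n_day, 0, inst_sd), n_site)
  vp <- pairs_fixture(
    site_id = rep(sprintf("S%02d", 1:n_site), each = n_day),
    site_type = "background",
    day = rep(1:n_day, times = n_site),
    monitor = as.vector(t(monitor)), model = as.vector(t(true)),
    instrument_error_variance = inst_sd^2
  )
  corrected <- estimate_error_params(vp, correct = TRUE)
  naive <- estimate_error_params(vp, correct = FALSE)
  expect_lt(naive$params$rho_T, 0.92)             # attenuated
  expect_equal(corrected$params$rho_T, 1, tolerance = 0.01)
  expect_lt(naive$params$lambda_T, 0.75)          # var inflated denominator
  expect_equal(corrected$params$lambda_T, 1, tolerance = 0.02)
  # excessive instrument variance is a named error
  vp$instrument_error_variance[] <- 1e4
  expect_error(estimate_error_params(vp), "instrument variance exceeds")
})

test_that("per-site temporal variant agrees with pooled on balanced planted data", {
  net <- make_monitor_network(c(background = 15), n_days = 300, seed = 6)
  vp <- make_validation_pairs(net, error_params(rho_T = 0.8, lambda_T = 1.5),
                              instrument_sd = 0, seed = 7)
  pooled <- estimate_error_params(vp, pooled = TRUE)
  persite <- estimate_error_params(vp, pooled = FALSE)
  expect_equal(persite$params$rho_T, pooled$params$rho_T, tolerance = 0.03)
  expect_equal(persite$params$lambda_T, pooled$params$lambda_T, tolerance = 0.08)
})

test_that("leave-out splits partition the network correctly", {
  ids47 <- sprintf("S%03d", 1:47)
  g <- leave_out_split(ids47, fraction = 0.1, seed = 1)
  expect_length(g, 10)
  sizes <- lengths(g)
  expect_true(all(sizes %in% c(4L, 5L)))
  expect_setequal(unlist(g), ids47)
  expect_equal(sum(sizes), 47L) # disjoint: union size equals total

  g2 <- leave_out_split(sprintf("S%02d", 1:10), fraction = 0.5, seed = 2)
  expect_length(g2, 2)
  expect_equal(lengths(g2), c(5L, 5L), ignore_attr = TRUE)

  expect_identical(leave_out_split(ids47, 0.1, seed = 9),
                   leave_out_split(ids47, 0.1, seed = 9))
  expect_error(leave_out_split(sprintf("S%d", 1:3), fraction = 0.1), "empty")
  expect_error(leave_out_split(ids47, fraction = 0), "fraction")
})

test_that("fewer than 3 sites rejects spatial estimation", {
  vp <- pairs_fixture(
    site_id = rep(c("A", "B"), each = 5), site_type = "background",
    day = rep(1:5, 2), monitor = rnorm(10, 40), model = rnorm(10, 40)
  )
  expect_error(estimate_error_params(vp), ">= 3 sites")
})
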