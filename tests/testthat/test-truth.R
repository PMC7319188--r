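test_that("degenerate noise gives the pure seasonal signal exactly", {
  geo <- tiny_geography(6)
  p <- truth_params(mu = 30, sigma_S = 0, amp = 5, sigma_C = 0, sigma_E = 0)
  fld <- simulate_truth(geo, p, n_days = 50, seed = 1)
  expected <- 30 + 5 * cos(2 * pi * (1:50) / 365.25)
  for (i in 1:6) expect_equal(unname(fld$conc[i, ]), expected, tolerance = 1e-12)
})

test_that("simulation is bit-identical under a fixed seed", {
  geo <- tiny_geography(10)
  f1 <- simulate_truth(geo, truth_params(), 30, seed = 42)
  f2 <- simulate_truth(geo, truth_params(), 30, seed = 42)
  expect_identical(f1$conc, f2$conc)
})

test_that("decomposition is exact and matches brute force", {
  # constant field
  fld <- tiny_field(5, 10)
  fld$conc[] <- 7.5
  cmp <- decompose_field(fld)
  expect_equal(unname(cmp$spatial), rep(7.5, 5))
  expect_true(all(cmp$temporal == 0))

  # reconstruction identity + zero row means on a random field
  fld2 <- tiny_field(8, 25, seed = 3)
  cmp2 <- decompose_field(fld2)
  expect_equal(cmp2$spatial + cmp2$temporal, fld2$conc, tolerance = 1e-12)
  expect_equal(unname(rowMeans(cmp2$temporal)), rep(0, 8), tolerance = 1e-12)

  # brute-force oracle with explicit loops on a 5 x 10 matrix
  set.seed(99)
  x <- matrix(rnorm(50, 40, 10), 5, 10)
  got <- decompose_field(x)
  for (i in 1:5) {
    m <- sum(x[i, ]) / 10
    expect_equal(unname(got$spatial[i]), m)
    for (t in 1:10) expect_equal(got$temporal[i, t], x[i, t] - m)
  }
})

test_that("spatial variance of area means matches the field covariance", {
  # E[sample var of a_i] under covariance S is (tr(S) - sum(S)/n)/(n - 1);
  # compare the mean over seeds against that closed form.
  geo <- make_geography(300, extent_km = 50, seed = 5)
  p <- truth_params(sigma_S = 5, phi_km = 10, amp = 0, sigma_C = 0,
                    sigma_E = 0)
  d <- as.matrix(dist(cbind(geo$x_km, geo$y_km)))
  S <- 25 * exp(-d / 10)
  n <- nrow(S)
  expect_var <- (sum(diag(S)) - sum(S) / n) / (n - 1)
  vs <- vapply(1:20, function(s) {
    var(decompose_field(simulate_truth(geo, p, 2, seed = s))$spatial)
  }, 0)
  expect_equal(mean(vs), expect_var, tolerance = 0.1)
  # and the sample variance is close to sigma_S^2 = 25 up to correlation loss
  expect_gt(mean(vs), 15)
  expect_lt(mean(vs), 30)
})

test_that("lag-1 autocorrelation of area-mean deviations follows AR(1) + noise mixture", {
  # areas average to c_t + mean(e_t): acf(1) = rho * sC^2 / (sC^2 + sE^2/n)
  n_areas <- 50
  p <- truth_params(sigma_S = 0, amp = 0, rho_AR = 0.5, sigma_C = 2,
                    sigma_E = 4)
  geo <- tiny_geography(n_areas, seed = 6)
  fld <- simulate_truth(geo, p, n_days = 4000, seed = 7)
  daily <- colMeans(fld$conc)
  a1 <- stats::acf(daily, plot = FALSE, lag.max = 1)$acf[2]
  expected <- 0.5 * 4 / (4 + 16 / n_areas)
  expect_equal(a1, expected, tolerance = 0.12)
})

test_that("stationary marginal variance adds up across components", {
  p <- truth_params(sigma_S = 3, phi_km = 5, amp = 4, rho_AR = 0.6,
                    sigma_C = 3, sigma_E = 5)
  geo <- make_geography(150, extent_km = 60, seed = 8)
  fld <- simulate_truth(geo, p, n_days = 1500, seed = 9)
  target <- 9 + 16 / 2 + 9 + 25 # sigma_S^2 + amp^2/2 + sigma_C^2 + sigma_E^2
  expect_equal(var(as.vector(fld$conc)), target, tolerance = 0.15)
})

test_that("duplicate centroids are jittered with a warning or rejected", {
  geo <- tiny_geography(5)
  geo$x_km[2] <- geo$x_km[1]
  geo$y_km[2] <- geo$y_km[1]
  expect_warning(simulate_truth(geo, truth_params(), 10, seed = 1), "jitter")
  expect_error(
    simulate_truth(geo, truth_params(), 10, seed = 1, on_duplicate = "error"),
    "singular"
  )
})

test_that("log-scale fields back-transform to strictly positive concentrations", {
  geo <- tiny_geography(10)
  fld <- simulate_truth(geo, truth_params_log(), 30, seed = 10)
  expect_identical(fld$scale, "log")
  nat <- as_natural(fld)
  expect_identical(nat$scale, "natural")
  expect_true(all(nat$conc > 0))
  expect_equal(nat$conc, exp(fld$conc), tolerance = 1e-12)
  expect_identical(as_natural(nat)$conc, nat$conc) # idempotent
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(truth_params(sigma_S = -1), "sigma_S")
  expect_error(truth_params(rho_AR = 1), "rho_AR")
  expect_error(truth_params(phi_km = 0), "phi_km")
})
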