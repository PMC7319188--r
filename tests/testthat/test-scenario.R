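test_that("the same spec run twice is identical, and order does not matter", {
  sp <- fast_spec(n_sims = 4)
  r1 <- run_scenario(sp, fit_method = "glm")
  r2 <- run_scenario(sp, fit_method = "glm")
  expect_identical(r1$fits, r2$fits)
  expect_identical(as.data.frame(r1$summary), as.data.frame(r2$summary))

  spA <- fast_spec(name = "A", base_seed = 31)
  spB <- fast_spec(name = "B", base_seed = 32)
  m1 <- run_manifest(list(spA, spB), fit_method = "glm")
  m2 <- run_manifest(list(spB, spA), fit_method = "glm")
  expect_identical(m1$scenarios$A$fits, m2$scenarios$A$fits)
})

test_that("manifest results have one row per scenario x horizon", {
  empty <- run_manifest(list())
  expect_equal(nrow(empty$results), 0L)
  expect_true(all(c("scenario", "horizon", "mean_est", "coverage", "power")
                  %in% names(empty$results)))

  two <- run_manifest(list(fast_spec("s1", n_sims = 2, base_seed = 41),
                           fast_spec("s2", n_sims = 2, base_seed = 42)),
                      fit_method = "glm")
  expect_equal(nrow(two$results), 4L)

  # paper-shaped grid: 4 pollution models x 2 site types -> 16 rows
  grid <- expand.grid(model = c("LUR", "dispersion", "hybrid1", "hybrid2"),
                      st = c("background", "roadside"),
                      stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(grid)), function(i) {
    fast_spec(paste0(grid$model[i], "_", grid$st[i]),
              n_areas = 12, n_days = 12, n_sims = 2, base_seed = 50 + i,
              pollution_model = grid$model[i], site_type = grid$st[i])
  })
  res <- run_manifest(specs, fit_method = "glm")
  expect_equal(nrow(res$results), 16L)
  expect_error(run_manifest(list(fast_spec("x"), fast_spec("x"))),
               "duplicate")
})

test_that("replicate seeds are pairwise distinct within and across scenarios", {
  seeds <- c(
    vapply(0:300, function(r) derive_seed(1, r, 1L), 0L),
    vapply(0:300, function(r) derive_seed(1, r, 2L), 0L),
    vapply(0:300, function(r) derive_seed(1, r, 3L), 0L),
    vapply(0:300, function(r) derive_seed(1 + 2^20, r, 1L), 0L)
  )
  expect_false(any(duplicated(seeds)))
  expect_true(all(seeds >= 0 & seeds < 2^31))
})

test_that("output tables are written and byte-stable", {
  sp <- fast_spec("stable", n_sims = 3, base_seed = 61)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_manifest(list(sp), out_dir = d1, fit_method = "glm")
  run_manifest(list(sp), out_dir = d2, fit_method = "glm")
  expect_identical(readLines(file.path(d1, "results.csv")),
                   readLines(file.path(d2, "results.csv")))
  expect_identical(readLines(file.path(d1, "fits_stable.csv")),
                   readLines(file.path(d2, "fits_stable.csv")))
})

test_that("YAML manifests parse into valid specs", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "root_seed: 99",
    "defaults:",
    "  n_areas: 15",
    "  n_days: 10",
    "  n_sims: 2",
    "  crf: {sigma_u: 0}",
    "scenarios:",
    "  - name: a",
    "    error: {rho_T: 0.8, lambda_T: 1.5}",
    "  - name: b",
    "    pollution_model: hybrid2",
    "    error: {rho_S: 0.9, lambda_S: 0.7}"
  ), path)
  specs <- read_manifest(path)
  expect_length(specs, 2)
  expect_equal(specs[[1]]$error$rho_T, 0.8)
  expect_equal(specs[[2]]$pollution_model, "hybrid2")
  expect_equal(specs[[1]]$base_seed, 99L)
  expect_equal(specs[[2]]$base_seed, 99L + 2^20)
  res <- run_manifest(specs, fit_method = "glm")
  expect_equal(nrow(res$results), 4L)

  # the shipped template parses
  tpl <- system.file("extdata", "manifest_template.yaml", package = "simexpo")
  specs_tpl <- read_manifest(tpl)
  expect_length(specs_tpl, 5)
  expect_identical(specs_tpl[[5]]$truth$scale, "log")
  expect_identical(specs_tpl[[5]]$error$error_scale, "proportional")
})

test_that("proportional scenarios demand a log-scale truth model", {
  expect_error(
    scenario_spec(error = error_params(error_scale = "proportional"),
                  truth = truth_params()),
    "log-scale"
  )
  sp <- scenario_spec(error = error_params(error_scale = "proportional"),
                      truth = truth_params_log(), n_areas = 12, n_days = 10,
                      n_sims = 2, crf = crf_set(sigma_u = 0))
  r <- run_scenario(sp, fit_method = "glm")
  expect_equal(nrow(r$fits), 2L)
})

test_that("systematic replicate failure aborts the scenario", {
  sp <- fast_spec(n_sims = 10)
  sp$crf <- crf_set(beta_LT = 2, sigma_u = 0) # overflows the rate cap
  expect_error(run_scenario(sp, fit_method = "glm"), "aborted")
})
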