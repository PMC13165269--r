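test_that("generators are deterministic under a fixed seed", {
  a <- simulate_titration(recovery_grid, 1000, ksv_per_M = 1.5e4,
                          noise_cv = 0.02, seed = 1)
  b <- simulate_titration(recovery_grid, 1000, ksv_per_M = 1.5e4,
                          noise_cv = 0.02, seed = 1)
  expect_identical(a$points, b$points)
  c <- simulate_titration(recovery_grid, 1000, ksv_per_M = 1.5e4,
                          noise_cv = 0.02, seed = 2)
  expect_false(identical(a$points$f_au, c$points$f_au))

  p1 <- simulate_panel(c(native = 10, glycated = 50),
                       c(native = 1, glycated = 2),
                       c(native = "native", glycated = "glycated"), seed = 9)
  p2 <- simulate_panel(c(native = 10, glycated = 50),
                       c(native = 1, glycated = 2),
                       c(native = "native", glycated = "glycated"), seed = 9)
  expect_identical(p1$groups, p2$groups)

  d1 <- simulate_dose_response(130, 2, c(50, 100, 200), noise_cv = 0.05,
                               seed = 3)
  d2 <- simulate_dose_response(130, 2, c(50, 100, 200), noise_cv = 0.05,
                               seed = 3)
  expect_identical(d1, d2)
})

test_that("seeded generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_titration(recovery_grid, 1000, ksv_per_M = 1e4,
                               noise_cv = 0.02, seed = 77))
  expect_identical(.Random.seed, before)
  draw_after <- runif(1)
  set.seed(123)
  expect_identical(runif(1), draw_after)
})

test_that("titration generator obeys its closed forms", {
  # F/F0 = 1 / (1 + KSV [Q]) for the static-quenching parameterisation
  ts <- simulate_titration(2e-5, 1000, ksv_per_M = 1.5e4, noise_cv = 0)
  expect_equal(ts$points$f_au / ts$f0_au, 1 / 1.3, tolerance = 1e-12)
  # isotherm parameterisation makes (F0-F)/F = Ka [Q]^n exactly
  q <- recovery_grid
  tb <- simulate_titration(q, 1000, ka_per_M = 0.863e4, n_sites = 0.98,
                           noise_cv = 0)
  lhs <- (tb$f0_au - tb$points$f_au) / tb$points$f_au
  expect_equal(lhs, 0.863e4 * q^0.98, tolerance = 1e-12)
  # the two parameterisations are mutually exclusive
  expect_error(simulate_titration(q, 1000, ksv_per_M = 1e4, ka_per_M = 1e4,
                                  n_sites = 1), "not both")
  expect_error(simulate_titration(q, 1000), "supply")
})

test_that("noisy titrations always satisfy the series invariants", {
  for (s in 1:25) {
    ts <- simulate_titration(recovery_grid, 1000, ksv_per_M = 2e3,
                             noise_cv = 0.05, seed = s)
    expect_true(all(ts$points$f_au > 0))
    expect_true(all(ts$points$f_au <= ts$f0_au))
  }
})

test_that("temperature-series generator is exactly van't Hoff consistent", {
  ka <- simulate_temperature_series(5396, 36.099, c(298, 303, 310))
  # regime of moderate binding: Ka ~ 1e4 M^-1 at 298 K
  expect_gt(ka$ka_per_M[1], 0.8e4)
  expect_lt(ka$ka_per_M[1], 0.95e4)
  # zero enthalpy makes Ka temperature-independent
  flat <- simulate_temperature_series(0, 20, c(280, 300, 320))
  expect_equal(diff(range(flat$ka_per_M)), 0)
  expect_error(simulate_temperature_series(100, 1, c(-3, 300)), "> 0")
})

test_that("panel generator respects means, truncation and zero-SD", {
  p <- simulate_panel(c(native = 10, glycated = 50),
                      c(native = 0, glycated = 0),
                      c(native = "native", glycated = "glycated"),
                      n_replicates = 4, seed = 1)
  expect_equal(p$groups$native, rep(10, 4))
  expect_equal(p$groups$glycated, rep(50, 4))
  # tight mean near zero still yields non-negative draws
  p2 <- simulate_panel(c(native = 0.5, glycated = 50),
                       c(native = 0.4, glycated = 1),
                       c(native = "native", glycated = "glycated"),
                       n_replicates = 50, seed = 2)
  expect_true(all(p2$groups$native >= 0))
  expect_error(simulate_panel(c(a = 1, b = 2), c(a = -1, b = 0),
                              c(a = "native", b = "glycated")), ">= 0")
})

test_that("every generated dataset passes its reader unchanged", {
  tf <- withr::local_tempfile(fileext = ".csv")
  for (s in 1:5) {
    ts <- simulate_titration(recovery_grid, 1000, ksv_per_M = 1.2e4,
                             noise_cv = 0.02, seed = s)
    write_titration_csv(ts, tf)
    expect_no_error(read_titration_csv(tf))
  }
})

test_that("spectral titration round-trips through peak extraction", {
  ksv <- 1.5e4
  q <- recovery_grid
  f0 <- 1000
  sp0 <- simulate_emission_spectrum(335, 25, f0)
  pk <- peak_intensity(sp0)
  spectra <- lapply(q, function(qi) {
    simulate_emission_spectrum(335, 25, f0 / (1 + ksv * qi))
  })
  f <- vapply(spectra, function(s) {
    peak_intensity(s, at_nm = pk$lambda_nm)$intensity_au
  }, numeric(1))
  fit <- stern_volmer_fit(titration_series(q, f, pk$intensity_au, 298))
  expect_equal(fit$ksv_per_M, ksv, tolerance = 1e-9)
})
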