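test_that("noiseless double-log data invert exactly", {
  for (pars in list(c(1e4, 1), c(0.863e4, 0.98), c(5e3, 1.2))) {
    ts <- simulate_titration(recovery_grid, 1000, ka_per_M = pars[1],
                             n_sites = pars[2], noise_cv = 0)
    fit <- double_log_fit(ts)
    expect_equal(fit$ka_per_M, pars[1], tolerance = 1e-6)
    expect_equal(fit$n_sites, pars[2], tolerance = 1e-6)
  }
})

test_that("double-log fit agrees with the (Ka, n) grid-search oracle", {
  set.seed(202)
  for (rep in 1:3) {
    ka <- 10^runif(1, 3, 5)
    n <- runif(1, 0.7, 1.3)
    ts <- simulate_titration(recovery_grid[1:8], 1000, ka_per_M = ka,
                             n_sites = n, noise_cv = 0)
    fit <- double_log_fit(ts)
    oracle <- oracle_double_log_grid(ts)
    expect_equal(fit$ka_per_M, unname(oracle["ka"]), tolerance = 0.02)
    expect_equal(fit$n_sites, unname(oracle["n"]), tolerance = 0.02)
  }
})

test_that("points with F >= F0 are excluded with a warning", {
  q <- c(1, 2, 3, 4, 5) * 1e-4
  f <- c(1000, 800, 700, 600, 500)  # first point unquenched
  ts <- titration_series(q, f, 1000, 298)
  expect_warning(fit <- double_log_fit(ts), "excluded")
  expect_equal(fit$n_points_used, 4)

  ts2 <- titration_series(q[1:3], c(1000, 1000, 900), 1000, 298)
  expect_warning(expect_error(double_log_fit(ts2), "insufficient"))
})

test_that("noisy parameter recovery meets the replicate-harness targets", {
  # 100 seeded titrations, 2% multiplicative noise, 10 points
  seeds <- 1:100
  ksv_err <- ka_err <- n_err <- numeric(length(seeds))
  for (i in seeds) {
    tq <- simulate_titration(recovery_grid, 1000, ksv_per_M = 1.525e4,
                             noise_cv = 0.02, seed = i)
    ksv_err[i] <- abs(stern_volmer_fit(tq)$ksv_per_M - 1.525e4) / 1.525e4
    tb <- simulate_titration(recovery_grid, 1000, ka_per_M = 0.863e4,
                             n_sites = 0.98, noise_cv = 0.02, seed = i + 4000)
    bf <- double_log_fit(tb)
    ka_err[i] <- abs(bf$ka_per_M - 0.863e4) / 0.863e4
    n_err[i] <- abs(bf$n_sites - 0.98) / 0.98
  }
  expect_lt(median(ksv_err), 0.10)
  expect_lt(median(ka_err), 0.10)
  expect_lt(median(n_err), 0.05)
})

test_that("site-marker displacement reproduces the printed-call pattern", {
  mk_quench <- function(ksv, marker = "none") {
    stern_volmer_fit(simulate_titration(recovery_grid, 1000, ksv_per_M = ksv,
                                        noise_cv = 0, marker = marker))
  }
  mk_bind <- function(ka, marker = "none") {
    double_log_fit(simulate_titration(recovery_grid, 1000, ka_per_M = ka,
                                      n_sites = 0.98, noise_cv = 0,
                                      marker = marker))
  }
  free_q <- mk_quench(ref_sites$free$ksv)
  free_b <- mk_bind(ref_sites$free$k)
  calls <- site_marker_analysis(
    free_q, free_b,
    list(
      warf = list(quench = mk_quench(ref_sites$warfarin$ksv, "warfarin-like"),
                  bind = mk_bind(ref_sites$warfarin$k, "warfarin-like")),
      ibu = list(quench = mk_quench(ref_sites$ibuprofen$ksv, "ibuprofen-like"),
                 bind = mk_bind(ref_sites$ibuprofen$k, "ibuprofen-like"))
    )
  )
  warf <- calls[calls$marker == "warfarin-like", ]
  ibu <- calls[calls$marker == "ibuprofen-like", ]
  expect_true(warf$displaced)
  expect_match(warf$assigned_site, "Sudlow site I")
  expect_false(ibu$displaced)
  expect_true(is.na(ibu$assigned_site))
  expect_equal(warf$k_ratio, 5.090 / 8.634, tolerance = 1e-3)
  expect_gt(ibu$k_ratio, 1)
})

test_that("identical constants with and without marker are not displaced", {
  ts <- simulate_titration(recovery_grid, 1000, ksv_per_M = 1.5e4,
                           noise_cv = 0)
  tb <- simulate_titration(recovery_grid, 1000, ka_per_M = 8.6e3,
                           n_sites = 1, noise_cv = 0)
  q <- stern_volmer_fit(ts); b <- double_log_fit(tb)
  calls <- site_marker_analysis(q, b, list(same = list(quench = q, bind = b)))
  expect_false(calls$displaced)
  expect_equal(calls$ksv_ratio, 1)
  expect_equal(calls$k_ratio, 1)
})
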