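test_that("titration series enforces its physical invariants", {
  q <- c(5, 10, 15) * 1e-6
  f <- c(930, 870, 820)
  ok <- titration_series(q, f, 1000, 298)
  expect_s3_class(ok, "titration_series")
  expect_equal(nrow(ok$points), 3)

  expect_error(titration_series(c(5e-6, 5e-6, 1e-5), f, 1000, 298),
               "duplicated")
  expect_error(titration_series(c(1e-5, 5e-6, 2e-5), f, 1000, 298),
               "strictly increasing")
  expect_error(titration_series(q, c(930, 0, 820), 1000, 298), "> 0")
  expect_error(titration_series(q, c(930, 870, 1100), 1000, 298),
               "exceeds F0")
  expect_error(titration_series(c(-1e-6, 5e-6, 1e-5), f, 1000, 298), "> 0")
  expect_error(titration_series(q, f, 1000, -5), "temperature_K")
})

test_that("reading a micromolar CSV converts concentrations to molar", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# temperature_K: 303", "# f0_au: 1200",
               "quencher_conc_uM,f_au", "5,1100", "10,1000", "15,930"), tf)
  ts <- read_titration_csv(tf)
  expect_equal(ts$points$quencher_conc_M, c(5, 10, 15) * 1e-6)
  expect_equal(ts$temperature_K, 303)
  expect_equal(ts$f0_au, 1200)
})

test_that("malformed titration files fail with named problems", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# temperature_K: 298", "# f0_au: 1000",
               "quencher_conc_uM,f_au", "5,900", "5,880", "10,850"), tf)
  expect_error(read_titration_csv(tf), "duplicated.*row 2")

  writeLines(c("# temperature_K: 298", "# f0_au: 1000",
               "quencher_conc_uM,f_au", "5,900", "10,0", "15,850"), tf)
  expect_error(read_titration_csv(tf), "row 2")

  writeLines(c("# f0_au: 1000", "quencher_conc_uM,f_au", "5,900"), tf)
  expect_error(read_titration_csv(tf), "temperature_K")

  writeLines(c("# temperature_K: 298", "# f0_au: 1000",
               "conc,f_au", "5,900"), tf)
  expect_error(read_titration_csv(tf), "quencher_conc")

  expect_error(read_titration_csv(file.path(tempdir(), "absent.csv")),
               "not found")
})

test_that("write-then-read round trip preserves all numeric fields exactly", {
  set.seed(11)
  for (rep in 1:5) {
    q <- sort(runif(8, 1e-6, 1e-3))
    f0 <- runif(1, 500, 5000)
    f <- f0 / (1 + runif(1, 1e3, 1e5) * q) * runif(8, 0.95, 1)
    ts <- titration_series(q, f, f0, runif(1, 280, 320),
                           marker = "warfarin-like")
    tf <- withr::local_tempfile(fileext = ".csv")
    write_titration_csv(ts, tf)
    back <- read_titration_csv(tf)
    expect_identical(back$points$quencher_conc_M, ts$points$quencher_conc_M)
    expect_identical(back$points$f_au, ts$points$f_au)
    expect_identical(back$f0_au, ts$f0_au)
    expect_identical(back$temperature_K, ts$temperature_K)
    expect_identical(back$marker, ts$marker)
  }
})

test_that("emission spectra validate and report their peak", {
  sp <- simulate_emission_spectrum(lambda_max_nm = 335, amplitude_au = 800)
  pk <- peak_intensity(sp)
  expect_equal(pk$lambda_nm, 335)
  expect_equal(pk$intensity_au, 800)
  # fixed-wavelength read returns the intensity at that grid point
  at <- peak_intensity(sp, at_nm = 335)
  expect_equal(at$intensity_au, 800)
  expect_error(emission_spectrum(c(300, 300, 310), c(1, 2, 3)),
               "strictly increasing")
  expect_error(emission_spectrum(c(300, 310), c(1, -2)), ">= 0")
})

test_that("optional corrections: per-point dilution and inner filter", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# temperature_K: 298", "# f0_au: 1000",
               "quencher_conc_uM,f_au,dilution_factor",
               "5,900,1.00", "10,800,1.05", "15,700,1.10"), tf)
  ts <- read_titration_csv(tf)
  expect_equal(ts$points$f_au, c(900, 800 * 1.05, 700 * 1.10))
  writeLines(c("# temperature_K: 298", "# f0_au: 1000",
               "quencher_conc_uM,f_au,dilution_factor",
               "5,900,0", "10,800,1", "15,700,1"), tf)
  expect_error(read_titration_csv(tf), "dilution_factor")

  # inner-filter hook: off unless called; F_corr = F * 10^((Aex+Aem)/2)
  base <- titration_series(c(5, 10, 15) * 1e-6, c(900, 800, 700), 1000, 298)
  corr <- inner_filter_correct(base, a_ex = c(0, 0.02, 0.04),
                               a_em = c(0, 0.02, 0.04))
  expect_equal(corr$points$f_au[1], 900)             # zero absorbance
  expect_equal(corr$points$f_au[2], 800 * 10^0.02)
  expect_true(all(corr$points$f_au <= corr$f0_au))
  expect_error(inner_filter_correct(base, 0.1, c(0, 0, 0)), "per titration")
})
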