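test_that("Beer-Lambert marker quantification and its linearities", {
  # a530 = 0.1 at 1 mg/mL: (0.1 / 12640) * 1e6 nmol/mg
  expect_equal(fructosamine_content(0.1, 1), 0.1 / 12640 * 1e6,
               tolerance = 1e-12)
  expect_equal(fructosamine_content(0, 1), 0)
  expect_equal(carbonyl_content(0.22, 1), 10, tolerance = 1e-12)
  expect_equal(carbonyl_content(0, 1), 0)

  base <- fructosamine_content(0.15, 2, dilution_factor = 3, path_cm = 0.5)
  # linear in absorbance and dilution
  expect_equal(fructosamine_content(0.30, 2, 3, 0.5), 2 * base)
  expect_equal(fructosamine_content(0.15, 2, 6, 0.5), 2 * base)
  # inverse-linear in protein concentration and path
  expect_equal(fructosamine_content(0.15, 1, 3, 0.5), 2 * base)
  expect_equal(fructosamine_content(0.15, 2, 3, 1), base / 2)
  expect_error(fructosamine_content(0.1, 0), "protein_mg_per_ml")
  expect_error(carbonyl_content(-0.1, 1), ">= 0")
})

test_that("lysine modification is relative to the native signal", {
  expect_equal(as.numeric(lysine_modification(1, 1)), 0)
  expect_equal(as.numeric(lysine_modification(1, 0)), 100)
  expect_equal(as.numeric(lysine_modification(1.00, 0.25)), 75)
  out <- lysine_modification(1, 1.2)  # stronger than native: clamped, flagged
  expect_equal(as.numeric(out), 0)
  expect_equal(attr(out, "out_of_range"), 1L)
  expect_error(lysine_modification(0, 0.5), "a335_native")
})

test_that("percent inhibition interpolates the glycation increment", {
  expect_equal(as.numeric(percent_inhibition(10, 90, 90)), 0)
  expect_equal(as.numeric(percent_inhibition(10, 90, 10)), 100)
  expect_equal(as.numeric(percent_inhibition(15.42, 89.89, 52.655)), 50,
               tolerance = 1e-12)
  # zero-baseline convention available by flag
  expect_equal(as.numeric(percent_inhibition(10, 80, 40, baseline = "zero")),
               50)
  # over-recovery flagged, not clamped
  flagged <- percent_inhibition(10, 90, 5)
  expect_gt(as.numeric(flagged), 100)
  expect_equal(attr(flagged, "out_of_range"), 1L)
  expect_error(percent_inhibition(50, 40, 30), "degenerate")
})

test_that("percent inhibition is affine-invariant", {
  set.seed(404)
  for (rep in 1:20) {
    n <- runif(1, 1, 50); g <- n + runif(1, 5, 100); t <- runif(1, n, g)
    base <- as.numeric(percent_inhibition(n, g, t))
    shift <- runif(1, -20, 20)
    scale <- runif(1, 0.1, 10)
    expect_equal(as.numeric(percent_inhibition(n + shift, g + shift,
                                               t + shift)), base,
                 tolerance = 1e-9)
    expect_equal(as.numeric(percent_inhibition(n * scale, g * scale,
                                               t * scale)), base,
                 tolerance = 1e-9)
  }
})

test_that("AGE inhibition mirrors the fivefold-rise regime", {
  expect_equal(as.numeric(age_inhibition(100, 500, 500)), 0)
  expect_equal(as.numeric(age_inhibition(100, 500, 300)), 50)
  over <- age_inhibition(100, 500, 80)  # below native: flagged over-recovery
  expect_gt(as.numeric(over), 100)
  expect_false(is.null(attr(over, "out_of_range")))
})

test_that("assay panels validate required roles and readings", {
  groups <- list(native = c(1, 1.1), glycated = c(5, 5.2), d200 = c(2, 2.1))
  roles <- c(native = "native", glycated = "glycated", d200 = "treated")
  p <- assay_panel("fructosamine", groups, roles, doses_uM = c(d200 = 200))
  expect_s3_class(p, "assay_panel")
  expect_error(assay_panel("fructosamine", groups[-1], roles[-1],
                           doses_uM = c(d200 = 200)), "native")
  expect_error(assay_panel("fructosamine", groups, roles), "doses_uM")
  bad <- groups; bad$native <- c(-1, 1)
  expect_error(assay_panel("fructosamine", bad, roles,
                           doses_uM = c(d200 = 200)), "non-negative")
})

test_that("panel summary aggregates replicates and derives inhibition", {
  # identical replicates: SD exactly zero, means exact
  groups <- list(native = rep(0.19, 4), glycated = rep(1.14, 4),
                 d200 = rep(0.5, 4), pc = rep(0.4, 4))
  roles <- c(native = "native", glycated = "glycated", d200 = "treated",
             pc = "positive_control")
  p <- assay_panel("fructosamine", groups, roles, doses_uM = c(d200 = 200))
  mr <- panel_summary(p)
  expect_equal(mr$group_stats$sd_raw, rep(0, 4))
  expect_equal(mr$group_stats$mean_raw, c(0.19, 1.14, 0.5, 0.4))
  # quantified values follow the extinction-coefficient conversion
  expect_equal(mr$group_stats$mean_value,
               c(0.19, 1.14, 0.5, 0.4) / 12640 * 1e6)
  # inhibition computed for treated and positive-control rows
  expect_equal(nrow(mr$pct_inhibition), 2)
  expect_equal(
    mr$pct_inhibition$pct_inhibition[mr$pct_inhibition$role == "treated"],
    as.numeric(percent_inhibition(0.19, 1.14, 0.5)))
  # identical replicates leave no residual variance for an ANOVA p-value,
  # but the fit must not error
  expect_true(is.na(mr$anova_p) || mr$anova_p < 1e-10)
})

test_that("a synthetic panel with known means round-trips through summary", {
  cfg <- demo_config(seed = 5)
  pc <- cfg$panels$fructosamine
  panel <- simulate_panel(pc$means, lapply(pc$sds, function(x) 0), pc$roles,
                          pc$doses_uM,
                          marker_kind = "fructosamine", seed = 5)
  mr <- panel_summary(panel)
  inh <- mr$pct_inhibition[mr$pct_inhibition$role == "treated", ]
  inh <- inh[order(inh$dose_uM), ]
  # noiseless panel reproduces the configured inhibition series
  expect_equal(inh$pct_inhibition, c(17.66, 32.80, 52.19, 71.5),
               tolerance = 1e-9)
  expect_true(all(diff(inh$pct_inhibition) > 0))
  # noisy panel: inhibition still increases with dose, ANOVA separates groups
  panel2 <- simulate_panel(pc$means, pc$sds, pc$roles, pc$doses_uM,
                           marker_kind = "fructosamine", seed = 6)
  mr2 <- panel_summary(panel2)
  inh2 <- mr2$pct_inhibition[mr2$pct_inhibition$role == "treated", ]
  expect_true(all(diff(inh2$pct_inhibition[order(inh2$dose_uM)]) > 0))
  expect_lt(mr2$anova_p, 0.05)
})

test_that("free-lysine panels report percent modification per group", {
  groups <- list(native = rep(1, 3), glycated = rep(0.24, 3),
                 d200 = rep(0.76, 3))
  roles <- c(native = "native", glycated = "glycated", d200 = "treated")
  p <- assay_panel("free_lysine", groups, roles, doses_uM = c(d200 = 200))
  mr <- panel_summary(p)
  expect_null(mr$pct_inhibition)
  mod <- mr$pct_modification
  expect_equal(mod$pct_modified[mod$group == "glycated"], 76)
  expect_equal(mod$pct_modified[mod$group == "d200"], 24)
})
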