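small_cfg <- function(...) {
  sim_config(n_per_group = c(low = 6, mid = 6, high = 6), n_genes = 300,
             n_repeats_per_class = c(SINE = 30, LINE = 20, LTR = 15,
                                     Satellite = 8, DNA = 12), ...)
}

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_cohort(small_cfg(seed = 5))
  b <- simulate_cohort(small_cfg(seed = 5))
  expect_identical(a$table$counts, b$table$counts)
  expect_identical(a$meta, b$meta)
  expect_identical(a$factor_expr, b$factor_expr)
  c <- simulate_cohort(small_cfg(seed = 6))
  expect_false(identical(a$table$counts, c$table$counts))
})

test_that("invalid configurations are rejected with listed violations", {
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(repeat_scaling = c(low = 0, mid = 1, high = 1.5)),
               "repeat_scaling")
  expect_error(sim_config(class_fractions = c(SINE = 2, LINE = 0.3,
                                              LTR = 0.09, Satellite = 0.002,
                                              DNA = 0.2)),
               "class_fractions")
})

test_that("truth aligns one-to-one with the emitted table", {
  sim <- simulate_counts(small_cfg(seed = 2))
  expect_equal(sim$truth$features$feature_id, rownames(sim$table$counts))
  expect_equal(sim$truth$samples$sample, sim$table$samples)
  expect_equal(sim$truth$features$kind, sim$table$features$kind)
  # repeat IDs follow the two-colon dialect, genes none
  expect_true(all(sim$table$features$repeat_class[
    sim$table$features$kind == "repeat"] %in%
      c("SINE", "LINE", "LTR", "Satellite", "DNA")))
})

test_that("flat repeat scaling removes the planted signal", {
  cfg <- small_cfg(seed = 3,
                   repeat_scaling = c(low = 1, mid = 1, high = 1))
  sim <- simulate_counts(cfg)
  norm <- normalize_log(sim$table)
  prof <- stratify_cohort(rg_profile(norm, sim$table$features))
  conc <- stratum_concordance(prof$stratum, sim$truth$samples$group)
  expect_lt(conc, 0.7)  # near chance, far below planted-signal recovery
})

test_that("survival generator respects censoring and effect direction", {
  cfg <- small_cfg(seed = 4, censor_rate = 0)
  sim <- simulate_counts(cfg)
  surv <- simulate_survival(sim$truth$samples, cfg)
  expect_true(all(surv$event == 1))
  expect_true(all(surv$survival_time > 0))

  # low-repeat group has the higher hazard: shorter mean survival at scale
  cfg2 <- sim_config(seed = 8, censor_rate = 0, log_hr_low = 2,
                     n_per_group = c(low = 150, mid = 150, high = 150))
  sim2 <- simulate_counts(cfg2)
  s2 <- simulate_survival(sim2$truth$samples, cfg2)
  g <- sim2$truth$samples$group
  expect_lt(mean(s2$survival_time[g == "low"]),
            mean(s2$survival_time[g != "low"]))
})

test_that("factor tiers hit their limiting correlations", {
  cfg <- small_cfg(seed = 9, tier_pcc = c(high = 1, mid = 0.4, none = 0))
  z <- rnorm(40)
  fac <- simulate_factor_expression(z, cfg)
  # rho = 1 and no residual noise: correlation exactly 1
  for (f in cfg$factor_tiers$high) {
    expect_equal(cor(z, fac$expr[f, ]), 1, tolerance = 1e-12)
  }
  expect_equal(nrow(fac$expr), 12)
  expect_error(simulate_factor_expression(rep(1, 10), cfg), "zero variance")
})
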