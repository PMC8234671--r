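test_that("product-limit estimate matches hand computation on toy data", {
  km <- km_estimate(surv_records(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(km$time, c(1, 2, 3))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(km$n_risk, c(3, 2, 1))

  # all censored: no steps
  km0 <- km_estimate(surv_records(c(5, 8), c(0, 0)))
  expect_equal(nrow(km0), 0)

  expect_error(km_estimate(surv_records(c(0, 1), c(1, 1))), "positive")
})

test_that("product-limit estimate agrees with a brute-force oracle", {
  set.seed(61)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    time <- sample(1:8, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    if (!any(event == 1)) event[1] <- 1
    km <- km_estimate(surv_records(time, event))
    oracle <- km_oracle(time, event)
    expect_equal(km$time, oracle$time)
    expect_equal(km$survival, oracle$survival, tolerance = 1e-12)
  }
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(62)
  time <- sort(sample(1:100, 15))
  km <- km_estimate(surv_records(time, rep(1, 15)))
  emp <- sapply(km$time, function(t) mean(time > t))
  expect_equal(km$survival, emp, tolerance = 1e-12)
})

test_that("log-rank test matches the O-E/V oracle and is symmetric", {
  A <- surv_records(c(1, 2), c(1, 1))
  B <- surv_records(c(3, 4), c(1, 1))
  lr <- logrank_test(A, B)
  oracle <- logrank_oracle(A$time, A$event, B$time, B$event)
  expect_equal(lr$chi2, oracle$chi2, tolerance = 1e-9)
  expect_equal(lr$p, oracle$p, tolerance = 1e-9)

  lr_swapped <- logrank_test(B, A)
  expect_equal(lr$chi2, lr_swapped$chi2, tolerance = 1e-12)

  set.seed(63)
  for (i in 1:50) {
    tA <- rexp(8, 0.1); eA <- rbinom(8, 1, 0.8)
    tB <- rexp(8, 0.2); eB <- rbinom(8, 1, 0.8)
    if (sum(eA) + sum(eB) == 0) eA[1] <- 1
    got <- logrank_test(surv_records(tA, eA), surv_records(tB, eB))
    want <- logrank_oracle(tA, eA, tB, eB)
    expect_equal(got$chi2, want$chi2, tolerance = 1e-8)
  }

  # two identical groups carry no signal
  same <- surv_records(c(1, 2, 3, 4), c(1, 1, 0, 1))
  lr0 <- logrank_test(same, same)
  expect_lt(lr0$chi2, 1e-10)
  expect_error(logrank_test(surv_records(1, 0), surv_records(2, 0)),
               "at least one event")
})

test_that("Cox fit validates inputs and reports Wald intervals", {
  set.seed(64)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, rate = 0.01 * exp(0.8 * x))
  rec <- data.frame(time = time, event = 1, group = ifelse(x == 1, "b", "a"),
                    age = rnorm(n, 60, 10))
  fit <- cox_fit(rec, c("group", "age"), reference = list(group = "a"))
  expect_true(fit$converged)
  expect_true(all(fit$table$hr > 0))
  expect_true(all(fit$table$ci_low <= fit$table$hr &
                    fit$table$hr <= fit$table$ci_high))
  expect_equal(fit$table$ci_low, exp(fit$table$coef - 1.96 * fit$table$se),
               tolerance = 1e-9)
  expect_equal(fit$table$ci_high, exp(fit$table$coef + 1.96 * fit$table$se),
               tolerance = 1e-9)

  ft <- forest_table(fit)
  expect_equal(ft$hr[ft$reference], 1)
  expect_equal(ft$level[ft$covariate == "group"], c("a", "b"))

  rec$flat <- 1
  expect_error(cox_fit(rec, "flat"), "constant covariate: flat")

  rec$age[1:3] <- NA
  expect_message(cox_fit(rec, c("group", "age")), "dropping 3")
})

test_that("declared reference levels steer the sign of the hazard ratio", {
  set.seed(65)
  n <- 80
  grp <- rep(c("low", "high"), each = n / 2)
  time <- rexp(n, rate = 0.01 * exp(1.0 * (grp == "low")))
  rec <- data.frame(time = time, event = 1, stratum = grp)
  fit_vs_high <- cox_fit(rec, "stratum", reference = list(stratum = "high"))
  expect_equal(fit_vs_high$table$term, "stratumlow")
  expect_gt(fit_vs_high$table$hr, 1)
  fit_vs_low <- cox_fit(rec, "stratum", reference = list(stratum = "low"))
  expect_lt(fit_vs_low$table$hr, 1)
  expect_equal(fit_vs_low$table$coef, -fit_vs_high$table$coef,
               tolerance = 1e-8)
})
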