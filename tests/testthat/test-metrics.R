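test_that("Wald interval matches hand computation and degenerates sanely", {
  ci <- proportion_ci(50, 100)
  z <- qnorm(0.975)
  expect_equal(ci$estimate, 0.5)
  expect_equal(ci$lower, 0.5 - z * sqrt(0.25 / 100))
  expect_equal(ci$upper, 0.5 + z * sqrt(0.25 / 100))
  expect_equal(round(ci$lower, 3), 0.402)
  expect_equal(round(ci$upper, 3), 0.598)
  # degenerate p = 0 collapses to a point
  ci0 <- proportion_ci(0, 10)
  expect_equal(c(ci0$lower, ci0$upper), c(0, 0))
  expect_error(proportion_ci(5, 0), "positive")
  expect_error(proportion_ci(11, 10), "\\[0, n\\]")
})

test_that("Wilson interval agrees with the score interval from prop.test", {
  for (case in list(c(56, 154), c(9, 49), c(1, 30), c(0, 12), c(29, 30))) {
    w <- proportion_ci(case[1], case[2], method = "wilson")
    ref <- prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(w$lower, ref[1], tolerance = 1e-8)
    expect_equal(w$upper, ref[2], tolerance = 1e-8)
    expect_true(w$lower >= 0 && w$upper <= 1)
  }
  # Wald and Wilson agree to 3 decimals at n = 10000, p = 0.5
  wd <- proportion_ci(5000, 10000)
  wl <- proportion_ci(5000, 10000, method = "wilson")
  expect_equal(round(c(wd$lower, wd$upper), 3), round(c(wl$lower, wl$upper), 3))
})

test_that("per-trigger performance rows conserve totals and render PPV", {
  run <- fixture_run()
  perf <- trigger_performance(run$hits, run$ades, run$reg)
  expect_equal(nrow(perf), 39)
  expect_equal(sum(perf$positive_count), nrow(run$hits))
  expect_equal(sum(perf$ade_hit_count),
               sum(ade_flagged_hits(run$hits, run$ades)))
  expect_true(all(perf$ade_hit_count <= perf$positive_count))
  expect_true(all(is.na(perf$ppv[perf$positive_count == 0])))
  # overall PPV equals the hit-weighted mean of defined per-trigger PPVs
  defined <- !is.na(perf$ppv)
  weighted <- sum(perf$ppv[defined] * perf$positive_count[defined]) /
    sum(perf$positive_count[defined])
  s <- cohort_summary(run$fx$cohort, run$hits, run$ades, run$reg)
  expect_equal(s$overall_ppv, weighted)
  # hits referencing a foreign trigger are rejected
  bad <- run$hits
  bad$trigger_id[1] <- "ZZ9"
  expect_error(trigger_performance(bad, run$ades, run$reg), "ZZ9")
})

test_that("cohort summary handles the no-hit and empty-cohort edges", {
  run <- fixture_run()
  expect_error(cohort_summary(list(), run$hits, run$ades, run$reg),
               "empty cohort")
  clean <- run$fx$cohort[250:260]
  hits <- screen_cohort(run$reg, clean)
  s <- cohort_summary(clean, hits, run$ades[0, ], run$reg)
  expect_equal(s$positive_record_rate, 0)
  expect_true(is.na(s$overall_ppv))
})

test_that("the three methods share the ADE denominator", {
  run <- fixture_run()
  s <- cohort_summary(run$fx$cohort, run$hits, run$ades, run$reg)
  mc <- method_comparison(run$ades, s$n_records, s$total_patient_days)
  expect_equal(mc$detected + mc$not_detected, rep(nrow(run$ades), 3))
  expect_true(all(mc$detection_rate >= 0 & mc$detection_rate <= 1))
})

test_that("risk model recovers a planted antibacterial log-odds ratio", {
  params <- sim_params(
    n_records = 2000,
    risk_model = list(intercept = -0.4, coefs = c(n_antibacterials = -1.3)))
  sim <- generate_cohort(params, seed = 7)
  hits <- screen_cohort(obstetric_registry(), sim$cohort)
  ades <- consolidate_ades(sim$cohort, sim$assessments, hits)
  fit <- fit_risk_model(sim$cohort, ades, covariates = "n_antibacterials")
  expect_equal(fit$estimate[fit$term == "n_antibacterials"], -1.3,
               tolerance = 0.25 / 1.3)  # within +/- 0.25 absolute
  expect_true(abs(fit$estimate[1] + 1.3) < 0.25)
  expect_lt(fit$p_value[1], 0.01)
  expect_true(fit$or_lower[1] < exp(-1.3) && exp(-1.3) < fit$or_upper[1])
})

test_that("a null covariate's CI covers OR = 1 at close to nominal rate", {
  # age has no effect under the default generator; over seeded replicates the
  # 95% Wald CI should cover 1 in >= 90% of fits
  covered <- 0L
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    params <- sim_params(
      n_records = 400,
      risk_model = list(intercept = -1.2, coefs = c(n_antibacterials = 0.4)))
    sim <- generate_cohort(params, seed = 1000 + r)
    ades <- consolidate_ades(sim$cohort, sim$assessments,
                             screen_cohort(obstetric_registry(), sim$cohort))
    fit <- fit_risk_model(sim$cohort, ades, covariates = c("age", "n_antibacterials"))
    ci <- fit[fit$term == "age", ]
    if (ci$or_lower <= 1 && 1 <= ci$or_upper) covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.9)
})

test_that("degenerate designs fail with clear messages", {
  run <- fixture_run()
  expect_error(
    fit_risk_model(run$fx$cohort, run$ades, covariates = "bogus"),
    "unknown covariate")
  # records 10-40 of the fixture are all vaginal deliveries -> constant
  sub <- run$fx$cohort[10:40]
  expect_error(
    fit_risk_model(sub, run$ades, covariates = "vaginal"),
    "constant across cohort")
})

test_that("severity and organ distributions use the ADE denominator", {
  run <- fixture_run()
  d <- distribution_summary(run$ades)
  expect_equal(sum(d$severity$count), nrow(run$ades))
  expect_equal(sum(d$organ_class$count), nrow(run$ades))
  expect_equal(sum(d$severity$percent), 100, tolerance = 0.05)
  one <- distribution_summary(run$ades[1, ])
  expect_equal(one$organ_class$percent, 100)
  expect_error(distribution_summary(run$ades[0, ]), "no ADEs")
})
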