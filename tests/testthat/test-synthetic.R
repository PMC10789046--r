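test_that("the study fixture satisfies its internal consistency contract", {
  fx <- build_study_fixture()
  expect_length(fx$cohort, 300)
  # passes inclusion with zero exclusions
  inc <- apply_inclusion_criteria(fx$cohort)
  expect_equal(nrow(inc$exclusions), 0)
  # demographic structure: mean age 27.45 (range 18-43), 1301 patient-days,
  # delivery mix 115/162/23
  tab <- cohort_tibble(fx$cohort)
  expect_equal(mean(tab$age), 27.45)
  expect_equal(range(tab$age), c(18, 43))
  expect_equal(sum(tab$length_of_stay), 1301)
  expect_true(all(tab$length_of_stay >= 3 & tab$length_of_stay <= 10))
  expect_equal(unname(table(tab$delivery_mode)[c("cesarean", "vaginal",
                                                 "fetal_preservation")]),
               table(c(rep("a", 115), rep("b", 162), rep("c", 23))) |>
                 unname())
  # planted truth cross-checks: module-wise hit totals 35 + 53 + 50 + 16
  counts <- study_trigger_counts()
  mod_tot <- tapply(counts$positives, counts$module, sum)
  expect_equal(as.integer(mod_tot[c("laboratory", "medication", "symptom",
                                    "outcome")]),
               c(35L, 53L, 50L, 16L))
  expect_equal(sum(counts$positives), 154)
  expect_equal(sum(counts$ades), 56)
  expect_equal(sum(counts$positives > 0), 22)
})

test_that("same seed gives byte-identical cohorts, different seeds differ", {
  p <- sim_params(n_records = 60)
  a <- generate_cohort(p, seed = 5)
  b <- generate_cohort(p, seed = 5)
  expect_identical(a, b)
  path_a <- withr::local_tempfile(fileext = ".jsonl")
  path_b <- withr::local_tempfile(fileext = ".jsonl")
  write_cohort(a$cohort, path_a); write_cohort(b$cohort, path_b)
  expect_identical(readLines(path_a), readLines(path_b))
  c_ <- generate_cohort(p, seed = 6)
  expect_false(identical(a$cohort, c_$cohort))
})

test_that("zero firing probabilities yield a hit-free cohort", {
  p <- sim_params(n_records = 40,
                  firing_prob = setNames(rep(0, 39),
                                         study_trigger_counts()$trigger_id),
                  ade_prob = setNames(rep(0, 39),
                                      study_trigger_counts()$trigger_id))
  sim <- generate_cohort(p, seed = 3)
  expect_equal(nrow(screen_cohort(obstetric_registry(), sim$cohort)), 0)
  expect_equal(nrow(sim$truth), 0)
})

test_that("an ADE probability on an inactive trigger is rejected", {
  fp <- setNames(rep(0, 39), study_trigger_counts()$trigger_id)
  ap <- fp; ap[["S3"]] <- 0.5
  expect_error(sim_params(firing_prob = fp, ade_prob = ap), "inactive trigger")
})

test_that("planted firing rates are recovered within binomial error", {
  ids <- study_trigger_counts()$trigger_id
  p0 <- 0.06
  params <- sim_params(n_records = 1500,
                       firing_prob = setNames(rep(p0, 39), ids),
                       ade_prob = setNames(rep(0.5, 39), ids))
  sim <- generate_cohort(params, seed = 21)
  hits <- screen_cohort(obstetric_registry(), sim$cohort)
  hc <- hit_counts(hits, obstetric_registry())
  bound <- 3 * sqrt(p0 * (1 - p0) / 1500)
  within <- abs(hc$n_records / 1500 - p0) <= bound
  # planting recipes are independent except that the coagulopathy recipe's
  # bleeding event also satisfies the bleeding symptom trigger, so allow a
  # few excursions (interference plus ordinary binomial tail draws)
  expect_gte(sum(within), 36)
  # the known interference is one-directional: S4 fires on its own plants
  # plus L8's, so its excess is roughly the L8 planting rate
  s4 <- hc$n_records[hc$trigger_id == "S4"] / 1500
  expect_gt(s4, p0)
  expect_lt(abs(s4 - (2 * p0 - p0^2)), 3 * sqrt(0.11 * 0.89 / 1500))
})

test_that("the full pipeline recovers planted per-trigger PPVs (truth oracle)", {
  ids <- study_trigger_counts()$trigger_id
  params <- sim_params(n_records = 1200,
                       firing_prob = setNames(rep(0.08, 39), ids),
                       ade_prob = setNames(rep(0.4, 39), ids))
  sim <- generate_cohort(params, seed = 31)
  reg <- obstetric_registry()
  hits <- screen_cohort(reg, sim$cohort)
  ades <- consolidate_ades(sim$cohort, sim$assessments, hits)
  perf <- trigger_performance(hits, ades, reg)
  truth_ppv <- tapply(sim$truth$is_ade, sim$truth$trigger_id, mean)
  # exclude the trigger pair with known recipe interference (L8 plants a
  # bleeding event read by S4)
  check <- setdiff(names(truth_ppv)[!is.na(truth_ppv)], "S4")
  for (id in check) {
    n <- perf$positive_count[perf$trigger_id == id]
    se <- sqrt(0.4 * 0.6 / n)
    expect_lte(abs(perf$ppv[perf$trigger_id == id] - truth_ppv[[id]]), 3 * se)
  }
})
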