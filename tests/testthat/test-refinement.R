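test_that("the study revision yields 35 triggers split 12/8/11/4", {
  run <- fixture_run()
  perf <- trigger_performance(run$hits, run$ades, run$reg)
  res <- refine_registry(run$reg, perf)
  expect_length(res$registry$triggers, 35)
  expect_equal(unlist(res$registry |> registry_tibble() |>
                        dplyr::count(module) |>
                        dplyr::arrange(module) |> dplyr::pull(n, name = module)),
               c(laboratory = 12L, medication = 8L, outcome = 4L, symptom = 11L))
  expect_setequal(res$report$dropped, c("M1", "S4", "S8", "S14"))
  expect_setequal(res$report$amended, c("M9", "M6"))
  # input registry untouched
  expect_length(run$reg$triggers, 39)
})

test_that("drop rules are idempotent and refuse triggers with positives", {
  run <- fixture_run()
  perf <- trigger_performance(run$hits, run$ades, run$reg)
  once <- refine_registry(run$reg, perf)
  twice <- refine_registry(once$registry,
                           trigger_performance(
                             screen_cohort(once$registry, run$fx$cohort[1:5]),
                             run$ades[0, ], once$registry))
  expect_equal(vapply(twice$registry$triggers, `[[`, "", "trigger_id"),
               vapply(once$registry$triggers, `[[`, "", "trigger_id"))
  expect_error(
    refine_registry(run$reg, perf,
                    list(revision_rule("drop_zero_hit", "M6"))),
    "36 positives")
  expect_error(
    refine_registry(run$reg, perf,
                    list(revision_rule("predicate_amendment", "ZZ9",
                                       pred_event("bleeding")))),
    "unknown trigger")
})

test_that("amended M9 requires magnesium above 5 mmol/L", {
  revised <- revised_registry()
  m9 <- revised$triggers[[which(vapply(revised$triggers, `[[`, "",
                                       "trigger_id") == "M9")]]
  base_exps <- list(
    default_exposure("D1", "magnesium_sulfate", start = 5, stop = 40),
    default_exposure("D2", "calcium_gluconate", start = 42, stop = 43,
                     route = "IV"))
  low <- make_record(exposures = base_exps,
                     labs = list(lab_result("LB1", "Mg", 4.0, "mmol/L", 41)))
  high <- make_record(exposures = base_exps,
                      labs = list(lab_result("LB1", "Mg", 5.5, "mmol/L", 41)))
  expect_equal(nrow(evaluate_trigger(m9, low)), 0)
  expect_equal(nrow(evaluate_trigger(m9, high)), 1)
})

test_that("amended M6 is restricted to non-cesarean patients", {
  revised <- revised_registry()
  m6 <- revised$triggers[[which(vapply(revised$triggers, `[[`, "",
                                       "trigger_id") == "M6")]]
  parts <- list(
    events = list(clinical_event("E1", "drug_induced_constipation", 30)),
    exposures = list(default_exposure("D1", "laxative", start = 32, stop = 34)))
  ces <- make_record(delivery = "cesarean", events = parts$events,
                     exposures = parts$exposures)
  vag <- make_record(delivery = "vaginal", events = parts$events,
                     exposures = parts$exposures)
  expect_equal(nrow(evaluate_trigger(m6, ces)), 0)
  expect_equal(nrow(evaluate_trigger(m6, vag)), 1)
})

test_that("amendments never increase screening hits on any cohort", {
  run <- fixture_run()
  revised <- revised_registry()
  shared <- intersect(vapply(run$reg$triggers, `[[`, "", "trigger_id"),
                      vapply(revised$triggers, `[[`, "", "trigger_id"))
  before <- hit_counts(run$hits, run$reg)
  after <- hit_counts(screen_cohort(revised, run$fx$cohort), revised)
  for (id in shared) {
    expect_lte(after$n_hits[after$trigger_id == id],
               before$n_hits[before$trigger_id == id])
  }
  sim <- generate_cohort(sim_params(n_records = 150), seed = 11)
  b <- hit_counts(screen_cohort(run$reg, sim$cohort), run$reg)
  a <- hit_counts(screen_cohort(revised, sim$cohort), revised)
  for (id in shared) {
    expect_lte(a$n_hits[a$trigger_id == id], b$n_hits[b$trigger_id == id])
  }
})

test_that("an empty rule list leaves the registry unchanged", {
  run <- fixture_run()
  perf <- trigger_performance(run$hits, run$ades, run$reg)
  res <- refine_registry(run$reg, perf, rules = list())
  expect_length(res$registry$triggers, 39)
  expect_length(res$report$dropped, 0)
  expect_length(res$report$amended, 0)
})
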