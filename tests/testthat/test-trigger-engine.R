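l1_def <- function() {
  reg <- obstetric_registry()
  reg$triggers[[which(vapply(reg$triggers, `[[`, "", "trigger_id") == "L1")]]
}

test_that("lab thresholds are strict and attach co-occurring suspect drugs", {
  rec <- make_record(
    labs = list(lab_result("LB1", "K", 3.1, "mmol/L", 30)),
    exposures = list(default_exposure("D1", "hypokalemic"))
  )
  hits <- evaluate_trigger(l1_def(), rec)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$evidence_ids[[1]], "LB1")
  expect_equal(hits$suspect_exposure_ids[[1]], "D1")
  # boundary: 3.3 does not satisfy "< 3.3"
  rec$labs[[1]]$value <- 3.3
  expect_equal(nrow(evaluate_trigger(l1_def(), rec)), 0)
})

test_that("strict mode drops hits without a co-occurring suspect exposure", {
  rec <- make_record(
    labs = list(lab_result("LB1", "K", 3.1, "mmol/L", 30)),
    exposures = list(default_exposure("D1", "antibiotic"))  # wrong class
  )
  expect_equal(nrow(evaluate_trigger(l1_def(), rec, mode = "screening")), 1)
  expect_equal(nrow(evaluate_trigger(l1_def(), rec, mode = "strict")), 0)
})

test_that("event exclusion flags veto firing", {
  reg <- obstetric_registry()
  s11 <- reg$triggers[[which(vapply(reg$triggers, `[[`, "", "trigger_id") == "S11")]]
  nausea <- make_record(events = list(
    clinical_event("E1", "gi_discomfort", 30,
                   exclusion_flags = "morning_sickness")))
  expect_equal(nrow(evaluate_trigger(s11, nausea)), 0)
  real <- make_record(events = list(clinical_event("E1", "gi_discomfort", 30)))
  expect_equal(nrow(evaluate_trigger(s11, real)), 1)
})

test_that("repeated same-day findings are capped at one hit per day", {
  rec <- make_record(labs = list(
    lab_result("LB1", "K", 3.1, "mmol/L", 25),
    lab_result("LB2", "K", 3.0, "mmol/L", 30),   # same calendar day
    lab_result("LB3", "K", 2.9, "mmol/L", 49)    # next day
  ))
  hits <- evaluate_trigger(l1_def(), rec)
  expect_equal(nrow(hits), 2)
  expect_equal(unlist(hits$evidence_ids), c("LB1", "LB3"))
})

test_that("a missing predicate attribute is a per-record error, others unaffected", {
  reg <- obstetric_registry()
  bad <- make_record("BAD", events = list(clinical_event("E1", "bp_elevated", 30)))
  good <- make_record("GOOD", labs = list(lab_result("LB1", "K", 3.1, "mmol/L", 30)))
  expect_warning(hits <- screen_cohort(reg, list(bad, good)), "BAD")
  expect_equal(unique(hits$record_id), "GOOD")
  report <- attr(hits, "report")
  expect_equal(report$record_id, "BAD")
  expect_match(report$error, "SBP")
})

test_that("built-in registries have the published rosters", {
  reg <- load_registry("obstetric_39")
  expect_length(reg$triggers, 39)
  mods <- table(vapply(reg$triggers, `[[`, "", "module"))
  expect_equal(as.integer(mods[c("laboratory", "medication", "symptom", "outcome")]),
               c(12, 9, 14, 4))
  gtt <- load_registry("gtt_medication")
  expect_length(gtt$triggers, 13)
  # the five comparator rules exercised by the study are present
  ids <- vapply(gtt$triggers, `[[`, "", "trigger_id")
  expect_true(all(c("GTT-M4", "GTT-M7", "GTT-M10", "GTT-M11", "GTT-M12") %in% ids))
  expect_length(load_registry("revised_35")$triggers, 35)
})

test_that("registries round-trip through YAML and reject duplicate ids", {
  reg <- obstetric_registry()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_registry(reg, path)
  back <- load_registry(path)
  expect_equal(length(back$triggers), 39)
  fx <- build_study_fixture()
  sub <- fx$cohort[1:30]
  expect_equal(screen_cohort(back, sub), screen_cohort(reg, sub),
               ignore_attr = TRUE)
  expect_error(
    trigger_registry("x", "1", list(l1_def(), l1_def())),
    "duplicate trigger_id")
})

test_that("strict-mode hits are a subset of screening-mode hits", {
  fx <- build_study_fixture()
  for (reg in list(obstetric_registry(), gtt_registry())) {
    sc <- screen_cohort(reg, fx$cohort, mode = "screening")
    st <- screen_cohort(reg, fx$cohort, mode = "strict")
    key <- function(h) paste(h$record_id, h$trigger_id, h$time)
    expect_true(all(key(st) %in% key(sc)))
  }
  sim <- generate_cohort(sim_params(n_records = 120), seed = 42)
  sc <- screen_cohort(obstetric_registry(), sim$cohort, mode = "screening")
  st <- screen_cohort(obstetric_registry(), sim$cohort, mode = "strict")
  key <- function(h) paste(h$record_id, h$trigger_id, h$time)
  expect_true(all(key(st) %in% key(sc)))
})

test_that("evaluation is invariant to record order and internal list order", {
  fx <- build_study_fixture()
  sub <- fx$cohort[c(1, 7, 9, 16, 49, 94, 104, 114)]
  base <- screen_cohort(obstetric_registry(), sub)
  perm <- sub[c(5, 3, 8, 1, 7, 2, 6, 4)]
  # also shuffle each record's internal lists
  perm <- lapply(perm, function(rec) {
    rec$labs <- rev(rec$labs); rec$events <- rev(rec$events)
    rec$exposures <- rev(rec$exposures)
    rec
  })
  shuffled <- screen_cohort(obstetric_registry(), perm)
  expect_equal(base$record_id, shuffled$record_id)
  expect_equal(base$trigger_id, shuffled$trigger_id)
  expect_equal(base$time, shuffled$time)
})

test_that("aggregated counts equal the sum of per-record counts", {
  run <- fixture_run()
  per_record <- vapply(run$fx$cohort, function(rec) {
    sum(run$hits$record_id == rec$record_id)
  }, 0L)
  expect_equal(sum(per_record), nrow(run$hits))
  hc <- hit_counts(run$hits, run$reg)
  expect_equal(sum(hc$n_hits), nrow(run$hits))
})
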