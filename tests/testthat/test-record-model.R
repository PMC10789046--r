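test_that("cohort JSONL round-trips through write and read", {
  fx <- build_study_fixture()
  sub <- fx$cohort[c(1, 7, 46, 104, 300)]
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_cohort(sub, path)
  back <- read_cohort(path)
  expect_length(back, 5)
  for (i in seq_along(sub)) expect_equal(unclass(back[[i]]), unclass(sub[[i]]))
  # a second round-trip is byte-identical
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_cohort(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("reading an empty file yields an empty cohort", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), path)
  expect_length(read_cohort(path), 0)
})

test_that("malformed lines are reported with line numbers and field names", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  good <- jsonlite::toJSON(unclass(make_record()), auto_unbox = TRUE)
  writeLines(c(good, "{not json"), path)
  expect_error(read_cohort(path), "line 2")
  # potassium reported in a non-whitelisted unit names the analyte
  bad <- make_record()
  bad$labs <- list(list(lab_id = "L1", analyte = "K", value = 3.3,
                        unit = "mg/dL", time = 10, is_baseline = FALSE))
  writeLines(jsonlite::toJSON(unclass(bad), auto_unbox = TRUE), path)
  expect_error(read_cohort(path), "analyte K")
})

test_that("record validation enforces structural invariants", {
  expect_error(make_record(stay_days = -1), "discharge_time")
  expect_error(
    make_record(events = list(clinical_event("E1", "not_a_code", 5))),
    "unknown event code")
  expect_error(
    make_record(exposures = list(default_exposure(classes = character()))),
    "empty drug_classes")
  expect_error(
    make_record(exposures = list(default_exposure(), default_exposure())),
    "duplicate id")
})

test_that("inclusion criteria keep eligible records and name exclusion reasons", {
  recs <- list(
    make_record("A", stay_days = 1.5),
    make_record("B", ga = 27),
    make_record("C", age = 15),
    make_record("D", exposures = list()),
    make_record("E")
  )
  res <- apply_inclusion_criteria(recs)
  expect_equal(vapply(res$records, `[[`, "", "record_id"), "E")
  expect_match(res$exclusions$reason[res$exclusions$record_id == "A"], "48h")
  expect_match(res$exclusions$reason[res$exclusions$record_id == "B"],
               "gestational")
  # a stay of exactly 48 h does not exceed 48 h
  res2 <- apply_inclusion_criteria(list(make_record("F", stay_days = 2)))
  expect_length(res2$records, 0)
  # idempotence
  twice <- apply_inclusion_criteria(res$records)
  expect_equal(length(twice$records), length(res$records))
  expect_equal(nrow(twice$exclusions), 0)
})

test_that("CSV ingestion assembles the same records as the JSONL path", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "record_id,age,gestational_age,admission_time,discharge_time,delivery_mode,diabetic_status,comorbidity_flags,srs_reported_event_ids",
    "P1,30,39,0,96,cesarean,none,,E1"
  ), file.path(dir, "patients.csv"))
  writeLines(c(
    "record_id,lab_id,analyte,value,unit,time,is_baseline",
    "P1,LB1,K,3.1,mmol/L,30,0"
  ), file.path(dir, "labs.csv"))
  writeLines(c(
    "record_id,exposure_id,drug_name,drug_classes,start_time,stop_time,abrupt_stop,route",
    "P1,D1,furosemide,hypokalemic;other,10,20,0,IV"
  ), file.path(dir, "exposures.csv"))
  writeLines(c(
    "record_id,event_id,code,time,attributes,exclusion_flags,is_neonate",
    "P1,E1,bp_elevated,30,SBP=150;DBP=92,,0",
    "P1,NE1,neonatal_compromise,31,,,1"
  ), file.path(dir, "events.csv"))
  cohort <- cohort_from_csv(file.path(dir, "patients.csv"),
                            file.path(dir, "labs.csv"),
                            file.path(dir, "exposures.csv"),
                            file.path(dir, "events.csv"))
  expect_length(cohort, 1)
  rec <- cohort[[1]]
  expect_equal(rec$labs[[1]]$analyte, "K")
  expect_equal(rec$exposures[[1]]$drug_classes, c("hypokalemic", "other"))
  expect_equal(rec$events[[1]]$attributes$SBP, 150)
  expect_equal(rec$neonate_events[[1]]$code, "neonatal_compromise")
  expect_equal(rec$srs_reported_event_ids, "E1")
  # and it screens identically to its JSONL serialization
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_cohort(cohort, path)
  h1 <- screen_cohort(obstetric_registry(), cohort)
  h2 <- screen_cohort(obstetric_registry(), read_cohort(path))
  expect_equal(h1$trigger_id, h2$trigger_id)
})
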