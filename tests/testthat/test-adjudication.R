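# independent oracle: enumerate the WHO-UMC cascade as literal rules
oracle_causality <- function(e) {
  if (e$information_quality == "insufficient_or_contradictory") "unassessable"
  else if (e$information_quality == "more_data_needed") "conditional"
  else if (e$time_relationship == "unknown") "unassessable"
  else if (e$time_relationship == "improbable") "unlikely"
  else if (e$time_relationship == "plausible" &&
           e$alternative_explanation == "excluded" &&
           e$dechallenge == "positive" &&
           (e$pharmacologically_definitive || e$rechallenge == "positive")) "certain"
  else if (e$alternative_explanation == "excluded" &&
           e$dechallenge == "positive") "probable"
  else "possible"
}

causality_grid <- function() {
  expand.grid(
    time_relationship = c("plausible", "reasonable", "improbable", "unknown"),
    alternative_explanation = c("excluded", "possible", "plausible"),
    dechallenge = c("positive", "negative", "not_done", "unknown"),
    rechallenge = c("positive", "negative", "not_done"),
    pharmacologically_definitive = c(TRUE, FALSE),
    information_quality = c("adequate", "more_data_needed",
                            "insufficient_or_contradictory"),
    stringsAsFactors = FALSE
  )
}

test_that("causality categories match the published definitions", {
  # definitive pharmacological event, clean dechallenge -> certain
  expect_equal(assess_causality(causality_evidence(
    "plausible", "excluded", dechallenge = "positive",
    pharmacologically_definitive = TRUE)), "certain")
  # reasonable timing but disease could explain it -> possible
  expect_equal(assess_causality(causality_evidence(
    "reasonable", "possible", dechallenge = "unknown")), "possible")
  # improbable timing -> unlikely
  expect_equal(assess_causality(causality_evidence(
    "improbable", "plausible")), "unlikely")
  # information gates come first
  expect_equal(assess_causality(causality_evidence(
    "plausible", "excluded", information_quality = "more_data_needed")),
    "conditional")
  expect_equal(assess_causality(causality_evidence(
    "plausible", "excluded",
    information_quality = "insufficient_or_contradictory")), "unassessable")
})

test_that("the cascade is total and deterministic over the full evidence grid", {
  grid <- causality_grid()
  cats <- c("certain", "probable", "possible", "unlikely", "conditional",
            "unassessable")
  for (i in seq_len(nrow(grid))) {
    e <- causality_evidence(grid$time_relationship[i],
                            grid$alternative_explanation[i],
                            grid$dechallenge[i], grid$rechallenge[i],
                            grid$pharmacologically_definitive[i],
                            grid$information_quality[i])
    got <- assess_causality(e)
    expect_true(got %in% cats)
    expect_identical(got, oracle_causality(e))
    expect_identical(got, assess_causality(e))  # repeat call, same answer
  }
})

test_that("improving dechallenge never demotes a drug-attributable event", {
  grid <- causality_grid()
  grid <- grid[grid$information_quality == "adequate" &
                 !grid$time_relationship %in% c("improbable", "unknown") &
                 grid$dechallenge == "unknown", ]
  rank <- c(possible = 1, probable = 2, certain = 3)
  for (i in seq_len(nrow(grid))) {
    before <- assess_causality(causality_evidence(
      grid$time_relationship[i], grid$alternative_explanation[i],
      "unknown", grid$rechallenge[i], grid$pharmacologically_definitive[i]))
    after <- assess_causality(causality_evidence(
      grid$time_relationship[i], grid$alternative_explanation[i],
      "positive", grid$rechallenge[i], grid$pharmacologically_definitive[i]))
    expect_gte(rank[[after]], rank[[before]])
  }
})

test_that("severity grading matches its precedence oracle and is monotone", {
  flags <- expand.grid(d = c(FALSE, TRUE), lt = c(FALSE, TRUE),
                       h = c(FALSE, TRUE), dis = c(FALSE, TRUE),
                       m = c(FALSE, TRUE))
  oracle <- function(d, lt, h, dis, m) {
    max(1L, if (m) 2L else 1L, if (h || dis) 3L else 1L,
        if (lt) 4L else 1L, if (d) 5L else 1L)
  }
  for (i in seq_len(nrow(flags))) {
    f <- flags[i, ]
    g <- grade_severity(f$d, f$lt, f$h, f$dis, f$m)
    expect_identical(g, oracle(f$d, f$lt, f$h, f$dis, f$m))
    # monotone: raising any single flag never lowers the grade
    for (j in 1:5) {
      f2 <- f; f2[[j]] <- TRUE
      expect_gte(grade_severity(f2$d, f2$lt, f2$h, f2$dis, f2$m), g)
    }
  }
  expect_identical(grade_severity(death_related = TRUE, TRUE, TRUE, TRUE, TRUE), 5L)
  expect_identical(grade_severity(), 1L)
  expect_identical(grade_severity(hospitalization_caused_or_prolonged = TRUE), 3L)
})

test_that("many hits on one event consolidate into a single ADE", {
  rec <- make_record(
    exposures = list(default_exposure("D1", "oxytocin")),
    events = list(
      clinical_event("E1", "bp_elevated", 30, list(SBP = 155, DBP = 95)),
      clinical_event("E2", "tachycardia_arrhythmia", 30, list(heart_rate = 150))
    ))
  hits <- screen_cohort(obstetric_registry(), list(rec))
  expect_equal(nrow(hits), 2)  # S3 and S13
  assess <- assessment_row("T1", c("E1", "E2"), "D1",
                           causality_evidence("plausible", "excluded",
                                              dechallenge = "positive",
                                              pharmacologically_definitive = TRUE))
  ades <- consolidate_ades(list(rec), assess, hits)
  expect_equal(nrow(ades), 1)
  expect_true(ades$detected_obstetric)
  expect_equal(sum(ade_flagged_hits(hits, ades)), 2)
})

test_that("only certain/probable assessments become ADEs; none is fine", {
  rec <- make_record(events = list(clinical_event("E1", "gi_discomfort", 30)))
  hits <- screen_cohort(obstetric_registry(), list(rec))
  possible <- assessment_row("T1", "E1", character(),
                             causality_evidence("reasonable", "possible"))
  expect_equal(nrow(consolidate_ades(list(rec), possible, hits)), 0)
  expect_equal(nrow(consolidate_ades(list(rec), possible[0, ], hits)), 0)
  # unknown finding ids are an error
  broken <- assessment_row("T1", "NOPE", character(),
                           causality_evidence("reasonable", "excluded",
                                              dechallenge = "positive"))
  expect_error(consolidate_ades(list(rec), broken, hits), "unknown finding")
})

test_that("an ADE reached by no trigger is retained with empty detection", {
  rec <- make_record(events = list(
    clinical_event("E1", "drug_induced_diarrhea", 30)))
  hits <- screen_cohort(obstetric_registry(), list(rec))
  expect_equal(nrow(hits), 0)
  assess <- assessment_row("T1", "E1", character(),
                           causality_evidence("reasonable", "excluded",
                                              dechallenge = "positive"))
  ades <- consolidate_ades(list(rec), assess, hits)
  expect_equal(nrow(ades), 1)
  expect_false(ades$detected_obstetric)
  expect_false(ades$detected_srs)
})

test_that("assessments round-trip through the CSV interchange form", {
  fx <- build_study_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_assessments_csv(fx$assessments, path)
  back <- read_assessments_csv(path)
  expect_equal(nrow(back), nrow(fx$assessments))
  expect_equal(back$event_ids, fx$assessments$event_ids)
  expect_equal(back$time_relationship, fx$assessments$time_relationship)
  expect_equal(back$death_related, fx$assessments$death_related)
})
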