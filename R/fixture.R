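# Deterministic study fixture.
#
# A 300-record synthetic cohort constructed (without randomness) so that the
# full pipeline reproduces the published review's count structure: 154
# obstetric-trigger hits on 120 records (22 of 39 triggers firing), 56
# ADE-linked hits collapsing to 48 trigger-detected events, 49 adjudicated
# ADEs in total (one reached by no trigger), the five-row GTT comparator
# outcome (31 hits, 10 ADE-linked, 9 distinct ADEs), 7 SRS-reported ADEs,
# severity split 17/27/5 across CTCAE grades 1-3, organ-class split
# 17/12/8/7 plus 5 across the remaining classes, and 1301 patient-days.
#
# Findings are planted at the granularity the triggers read; the allocation
# of hits to records (which the source counts do not determine) is fixed and
# documented in the package vignette.

fx_rid <- function(i) sprintf("R%03d", i)

# record groups (fixture layout; indices into 1:300) -----------------------
fx_groups <- function() {
  list(
    s3_s13 = 1:4,       # elevated BP + tachycardia after oxytocin (ADE)
    s5_o1 = 5L,         # PPH -> ICU (ADE)
    s2_o1 = 6L,         # hypotension -> ICU (ADE)
    s11_m8 = 7L,        # vomiting + antiemetic (ADE; GTT anti-emetic)
    s1_m2 = 8L,         # allergy + diphenhydramine (ADE; GTT diphenhydramine)
    s3 = 9:15,          # elevated BP (ADE; record 9 also GTT abrupt stop)
    s2 = 16:20,         # hypotension (ADE; record 16 also GTT abrupt stop)
    s5 = 21:22, s6 = 23:27, o3 = 28:34, s11 = 35:42, s1 = 43L,
    s10 = 44:45, l11_ade = 46L, m6_ade = 47:48,
    m6_m9 = 49:63,      # post-cesarean laxative + calcium gluconate (no ADE)
    m6_l5 = 64:71, m6 = 72:82, l5 = 83:91,
    s6_o3 = 92:93, s1_s2 = 94L, s2_plain = 95:97, o3_plain = 98:99,
    s5_plain = 100L, o2 = 101:103, l1 = 104L, l6 = 105:108,
    l9 = 109:111, l10 = 112L, l11 = 113L, l12 = 114:120,
    excl_s11 = 150L, excl_l9 = 151L, excl_s3 = 152L,
    undetected_ade = 300L
  )
}

fx_grade_for <- function(i) {
  if (i %in% c(5, 6, 9, 28, 46)) return(3L)
  if (i %in% c(1:4, 7, 8, 10:27, 29:31)) return(2L)
  1L
}

fx_srs_records <- function() c(1, 9, 16, 23, 28, 35, 47)

fx_causality <- function(i) {
  if (i <= 10) {
    causality_evidence("plausible", "excluded", dechallenge = "positive",
                       pharmacologically_definitive = TRUE)
  } else {
    causality_evidence("reasonable", "excluded", dechallenge = "positive")
  }
}

fx_severity <- function(grade) {
  switch(grade,
         list(),
         list(moderate_intervention_or_instrumental_adl_limited = TRUE),
         list(hospitalization_caused_or_prolonged = TRUE,
              moderate_intervention_or_instrumental_adl_limited = TRUE))
}

#' Build the deterministic study fixture
#'
#' Constructs the 300-record fixture cohort, its reviewer assessment table
#' and a truth annotation of every planted trigger finding. The build is
#' fully deterministic (no randomness) and passes the inclusion filter with
#' zero exclusions.
#'
#' @return A list: `cohort` (300 `patient_record`s), `assessments`
#'   (assessment tibble, one row per reviewed event), `truth` (tibble of
#'   planted findings: `record_id`, `trigger_id`, `is_ade`).
#' @export
build_study_fixture <- function() {
  g <- fx_groups()
  stays <- c(rep(10, 3), rep(9, 4), rep(8, 5), rep(7, 9), rep(6, 18),
             rep(5, 48), rep(3, 68), rep(4, 145))
  ages <- rep(27, 300)
  ages[1] <- 18; ages[2] <- 43; ages[3:130] <- 28
  delivery <- character(300)
  delivery[c(1:48, 83:120, 202:277)] <- "vaginal"
  delivery[c(49:82, 121:201)] <- "cesarean"
  delivery[278:300] <- "fetal_preservation"

  cohort <- vector("list", 300)
  assessments <- list()
  truth <- list()

  add_truth <- function(i, trig, ade) {
    truth[[length(truth) + 1]] <<- tibble::tibble(
      record_id = fx_rid(i), trigger_id = trig, is_ade = ade)
  }
  add_assessment <- function(i, event_ids, impl_ids) {
    grade <- fx_grade_for(i)
    assessments[[length(assessments) + 1]] <<- assessment_row(
      fx_rid(i), event_ids, impl_ids, fx_causality(i), fx_severity(grade))
  }
  add_possible_assessment <- function(i, event_ids, impl_ids) {
    assessments[[length(assessments) + 1]] <<- assessment_row(
      fx_rid(i), event_ids, impl_ids,
      causality_evidence("reasonable", "possible", dechallenge = "unknown"),
      list())
  }

  drug <- medication_exposure
  ev <- clinical_event
  lab <- lab_result

  for (i in 1:300) {
    labs <- list(); events <- list(); nevents <- list(); exps <- list()
    comorb <- character(); srs <- character()

    if (i %in% g$s3_s13) {
      exps <- list(drug("D1", "oxytocin", "oxytocin", 10, 20))
      events <- list(ev("E1", "bp_elevated", 30, list(SBP = 155, DBP = 95)),
                     ev("E2", "tachycardia_arrhythmia", 30, list(heart_rate = 150)))
      add_assessment(i, c("E1", "E2"), "D1")
      add_truth(i, "S3", TRUE); add_truth(i, "S13", TRUE)
    } else if (i %in% g$s5_o1) {
      exps <- list(drug("D1", "magnesium sulfate", "magnesium_sulfate", 10, 20))
      events <- list(ev("E1", "weak_contraction_pph", 30),
                     ev("E2", "icu_admission_rescue", 32))
      add_assessment(i, c("E1", "E2"), "D1")
      add_truth(i, "S5", TRUE); add_truth(i, "O1", TRUE)
    } else if (i %in% g$s2_o1) {
      exps <- list(drug("D1", "magnesium sulfate", "magnesium_sulfate", 10, 20))
      events <- list(ev("E1", "hypotension_fall", 30),
                     ev("E2", "icu_admission_rescue", 32))
      add_assessment(i, c("E1", "E2"), "D1")
      add_truth(i, "S2", TRUE); add_truth(i, "O1", TRUE)
    } else if (i %in% g$s11_m8) {
      exps <- list(drug("D1", "carboprost", "prostaglandin", 10, 20),
                   drug("D2", "metoclopramide", "antiemetic", 32, 33))
      events <- list(ev("E1", "gi_discomfort", 30),
                     ev("E2", "drug_induced_vomiting", 30))
      # finding trail includes the antiemetic given for the event
      add_assessment(i, c("E1", "E2", "D2"), "D1")
      add_truth(i, "S11", TRUE); add_truth(i, "M8", TRUE)
    } else if (i %in% g$s1_m2) {
      exps <- list(drug("D1", "cefazolin", "antibiotic", 10, 20),
                   drug("D2", "diphenhydramine",
                        c("antihistamine", "diphenhydramine"), 32, 33))
      events <- list(ev("E1", "skin_allergic_reaction", 30))
      # finding trail includes the antihistamine given for the reaction
      add_assessment(i, c("E1", "D2"), "D1")
      add_truth(i, "S1", TRUE); add_truth(i, "M2", TRUE)
    } else if (i %in% g$s3) {
      exps <- list(drug("D1", "ergometrine", "ergonovine", 10, 20,
                        abrupt_stop = (i == 9)))
      events <- list(ev("E1", "bp_elevated", 30, list(SBP = 150, DBP = 92)))
      add_assessment(i, "E1", "D1")
      add_truth(i, "S3", TRUE)
    } else if (i %in% g$s2) {
      exps <- list(drug("D1", "magnesium sulfate", "magnesium_sulfate", 10, 20))
      if (i == 16) {
        exps <- c(exps, list(drug("D2", "diazepam", "sedative_hypnotic", 5, 8,
                                  abrupt_stop = TRUE)))
      }
      events <- list(ev("E1", "hypotension_fall", 30))
      add_assessment(i, "E1", if (i == 16) c("D1", "D2") else "D1")
      add_truth(i, "S2", TRUE)
    } else if (i %in% g$s5) {
      exps <- list(drug("D1", "magnesium sulfate", "magnesium_sulfate", 10, 20))
      events <- list(ev("E1", "weak_contraction_pph", 30))
      add_assessment(i, "E1", "D1")
      add_truth(i, "S5", TRUE)
    } else if (i %in% g$s6) {
      exps <- list(drug("D1", "oxytocin", "oxytocin", 10, 20))
      events <- list(ev("E1", "uterine_hyperstimulation", 30))
      add_assessment(i, "E1", "D1")
      add_truth(i, "S6", TRUE)
    } else if (i %in% g$o3) {
      exps <- list(drug("D1", "oxytocin", "oxytocin", 10, 20))
      nevents <- list(ev("NE1", "neonatal_compromise", 30))
      add_assessment(i, "NE1", "D1")
      add_truth(i, "O3", TRUE)
    } else if (i %in% g$s11) {
      exps <- list(drug("D1", "misoprostol", "prostaglandin", 10, 20))
      events <- list(ev("E1", "gi_discomfort", 30))
      add_assessment(i, "E1", "D1")
      add_truth(i, "S11", TRUE)
    } else if (i %in% g$s1) {
      exps <- list(drug("D1", "ceftriaxone", "antibiotic", 10, 20))
      events <- list(ev("E1", "skin_allergic_reaction", 30))
      add_assessment(i, "E1", "D1")
      add_truth(i, "S1", TRUE)
    } else if (i %in% g$s10) {
      exps <- list(drug("D1", "cefuroxime", "antibiotic", 10, 20))
      events <- list(ev("E1", "neuro_symptom", 30))
      add_assessment(i, "E1", "D1")
      add_truth(i, "S10", TRUE)
    } else if (i %in% g$l11_ade) {
      exps <- list(drug("D1", "latamoxef", c("leukopenic", "antibiotic"), 10, 20))
      labs <- list(lab("LB1", "WBC", 4.5, "10^9/L", 30))
      add_assessment(i, "LB1", "D1")
      add_truth(i, "L11", TRUE)
    } else if (i %in% g$m6_ade) {
      exps <- list(drug("D1", "pethidine", "opioid_analgesic", 10, 20),
                   drug("D2", "lactulose", "laxative", 32, 34))
      events <- list(ev("E1", "drug_induced_constipation", 30))
      add_assessment(i, "E1", "D1")
      add_truth(i, "M6", TRUE)
    } else if (i %in% g$m6_m9) {
      exps <- list(drug("D1", "lactulose", "laxative", 32, 34),
                   drug("D2", "magnesium sulfate", "magnesium_sulfate", 5, 40),
                   drug("D3", "calcium gluconate", "calcium_gluconate", 42, 43,
                        route = "IV"))
      events <- list(ev("E1", "drug_induced_constipation", 30))
      add_truth(i, "M6", FALSE); add_truth(i, "M9", FALSE)
    } else if (i %in% g$m6_l5) {
      exps <- list(drug("D1", "lactulose", "laxative", 32, 34))
      events <- list(ev("E1", "drug_induced_constipation", 30))
      labs <- list(lab("LB1", "BG_fasting", 2.5, "mmol/L", 30))
      add_truth(i, "M6", FALSE); add_truth(i, "L5", FALSE)
    } else if (i %in% g$m6) {
      exps <- list(drug("D1", "pethidine", "opioid_analgesic", 10, 20),
                   drug("D2", "lactulose", "laxative", 32, 34))
      events <- list(ev("E1", "drug_induced_constipation", 30))
      add_truth(i, "M6", FALSE)
    } else if (i %in% g$l5) {
      exps <- list(drug("D1", "cefazolin", "antibiotic", 10, 20))
      labs <- list(lab("LB1", "BG_fasting", 2.5, "mmol/L", 30))
      add_truth(i, "L5", FALSE)
    } else if (i %in% g$s6_o3) {
      exps <- list(drug("D1", "oxytocin", "oxytocin", 10, 20))
      events <- list(ev("E1", "uterine_hyperstimulation", 30))
      nevents <- list(ev("NE1", "neonatal_compromise", 31))
      add_possible_assessment(i, c("E1", "NE1"), "D1")
      add_truth(i, "S6", FALSE); add_truth(i, "O3", FALSE)
    } else if (i %in% g$s1_s2) {
      exps <- list(drug("D1", "cefazolin", "antibiotic", 10, 20))
      events <- list(ev("E1", "skin_allergic_reaction", 30),
                     ev("E2", "hypotension_fall", 31))
      add_truth(i, "S1", FALSE); add_truth(i, "S2", FALSE)
    } else if (i %in% g$s2_plain) {
      exps <- list(drug("D1", "labetalol", "antihypertensive", 10, 20))
      events <- list(ev("E1", "hypotension_fall", 30))
      add_truth(i, "S2", FALSE)
    } else if (i %in% g$o3_plain) {
      exps <- list(drug("D1", "oxytocin", "oxytocin", 10, 20))
      nevents <- list(ev("NE1", "neonatal_compromise", 30))
      add_truth(i, "O3", FALSE)
    } else if (i %in% g$s5_plain) {
      exps <- list(drug("D1", "magnesium sulfate", "magnesium_sulfate", 10, 20))
      events <- list(ev("E1", "weak_contraction_pph", 30))
      add_truth(i, "S5", FALSE)
    } else if (i %in% g$o2) {
      exps <- list(drug("D1", "methyldopa",
                        c("long_term_maintenance", "antihypertensive"), 0, 30))
      events <- list(ev("E1", "abrupt_med_stop_event", 30))
      add_truth(i, "O2", FALSE)
    } else if (i %in% g$l1) {
      exps <- list(drug("D1", "furosemide", "hypokalemic", 10, 20))
      labs <- list(lab("LB1", "K", 3.1, "mmol/L", 30))
      add_truth(i, "L1", FALSE)
    } else if (i %in% g$l6) {
      exps <- list(drug("D1", "dexamethasone",
                        c("glucocorticoid", "hyperglycemic"), 10, 20))
      labs <- list(lab("LB1", "BG_fasting", 7.0, "mmol/L", 30))
      add_truth(i, "L6", FALSE)
    } else if (i %in% g$l9) {
      exps <- list(drug("D1", "heparin",
                        c("heparin", "thrombocytopenic", "anticoagulant"), 10, 20))
      labs <- list(lab("LB1", "platelets", 40, "10^9/L", 30))
      add_truth(i, "L9", FALSE)
    } else if (i %in% g$l10) {
      exps <- list(drug("D1", "propylthiouracil", "antithyroid", 10, 20))
      labs <- list(lab("LB1", "TSH", 5.0, "mIU/L", 30))
      add_truth(i, "L10", FALSE)
    } else if (i %in% g$l11) {
      exps <- list(drug("D1", "latamoxef", c("leukopenic", "antibiotic"), 10, 20))
      labs <- list(lab("LB1", "WBC", 5.0, "10^9/L", 30))
      add_truth(i, "L11", FALSE)
    } else if (i %in% g$l12) {
      exps <- list(drug("D1", "erythromycin", c("hepatotoxic", "antibiotic"), 10, 20))
      labs <- list(lab("LB1", "ALT", 150, "U/L", 30),
                   lab("LB2", "ALP", 80, "U/L", 30))
      add_truth(i, "L12", FALSE)
    } else if (i %in% g$excl_s11) {
      # nausea of pregnancy: flagged, must not fire the GI trigger
      exps <- list(drug("D1", "cefazolin", "antibiotic", 10, 20))
      events <- list(ev("E1", "gi_discomfort", 30,
                        exclusion_flags = "morning_sickness"))
    } else if (i %in% g$excl_l9) {
      # physiologic thrombocytopenia of pregnancy: record flag vetoes L9
      exps <- list(drug("D1", "iron supplement", "other", 10, 20))
      labs <- list(lab("LB1", "platelets", 45, "10^9/L", 30))
      comorb <- "physiologic_thrombocytopenia"
    } else if (i %in% g$excl_s3) {
      # poorly controlled chronic hypertension: record flag vetoes S3
      exps <- list(drug("D1", "nifedipine", "antihypertensive", 10, 20))
      events <- list(ev("E1", "bp_elevated", 30, list(SBP = 160, DBP = 95)))
      comorb <- "preexisting_hypertension_uncontrolled"
    } else if (i %in% g$undetected_ade) {
      # medication-error ADE documented in the chart but matching no clue
      exps <- list(drug("D1", "misoprostol", "prostaglandin", 10, 20))
      events <- list(ev("E1", "drug_induced_diarrhea", 30))
      add_assessment(i, "E1", "D1")
    } else {
      exps <- list(drug("D1", "cefazolin", "antibiotic", 10, 20))
    }

    if (i %in% fx_srs_records()) {
      first_ev <- if (length(events)) events[[1]]$event_id else nevents[[1]]$event_id
      srs <- first_ev
    }

    cohort[[i]] <- patient_record(
      record_id = fx_rid(i), age = ages[i],
      gestational_age = if (delivery[i] == "fetal_preservation") 32 else 38,
      admission_time = 0, discharge_time = stays[i] * 24,
      delivery_mode = delivery[i], diabetic_status = "none",
      comorbidity_flags = comorb, labs = labs, exposures = exps,
      events = events, neonate_events = nevents,
      srs_reported_event_ids = srs
    )
  }

  list(cohort = as_cohort(cohort),
       assessments = dplyr::bind_rows(assessments),
       truth = dplyr::bind_rows(truth))
}

#' Write the study fixture to a directory
#'
#' Materialises the fixture as `cohort.jsonl` and `assessments.csv`, the
#' input formats consumed by [run_pipeline()].
#'
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study_fixture <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- build_study_fixture()
  write_cohort(fx$cohort, file.path(dir, "cohort.jsonl"))
  write_assessments_csv(fx$assessments, file.path(dir, "assessments.csv"))
  invisible(dir)
}
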