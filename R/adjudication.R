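# Adjudication: WHO-UMC causality, CTCAE v5 severity, and consolidation of
# trigger hits plus reviewer evidence into adjudicated adverse drug events.

.time_rel <- c("plausible", "reasonable", "improbable", "unknown")
.alt_expl <- c("excluded", "possible", "plausible")
.dechallenge <- c("positive", "negative", "not_done", "unknown")
.rechallenge <- c("positive", "negative", "not_done")
.info_quality <- c("adequate", "more_data_needed", "insufficient_or_contradictory")

#' Structured causality evidence
#'
#' The six structured judgements a reviewer records for a candidate
#' drug-event pair, feeding the WHO-UMC cascade. The three-level
#' `alternative_explanation` scale folds "unlikely to be attributed to
#' disease or other drugs" into `"excluded"`.
#'
#' @param time_relationship `"plausible"`, `"reasonable"`, `"improbable"` or
#'   `"unknown"`.
#' @param alternative_explanation `"excluded"`, `"possible"` or `"plausible"`.
#' @param dechallenge Response to withdrawal: `"positive"`, `"negative"`,
#'   `"not_done"`, `"unknown"`.
#' @param rechallenge `"positive"`, `"negative"`, `"not_done"`.
#' @param pharmacologically_definitive Is the event an objective, recognized
#'   pharmacological phenomenon?
#' @param information_quality `"adequate"`, `"more_data_needed"`,
#'   `"insufficient_or_contradictory"`.
#' @return A list of class `causality_evidence`.
#' @export
causality_evidence <- function(time_relationship, alternative_explanation,
                               dechallenge = "not_done",
                               rechallenge = "not_done",
                               pharmacologically_definitive = FALSE,
                               information_quality = "adequate") {
  time_relationship <- match.arg(time_relationship, .time_rel)
  alternative_explanation <- match.arg(alternative_explanation, .alt_expl)
  dechallenge <- match.arg(dechallenge, .dechallenge)
  rechallenge <- match.arg(rechallenge, .rechallenge)
  information_quality <- match.arg(information_quality, .info_quality)
  structure(list(time_relationship = time_relationship,
                 alternative_explanation = alternative_explanation,
                 dechallenge = dechallenge, rechallenge = rechallenge,
                 pharmacologically_definitive = isTRUE(pharmacologically_definitive),
                 information_quality = information_quality),
            class = "causality_evidence")
}

#' WHO-UMC causality assessment
#'
#' Deterministic first-match cascade over structured evidence; each branch
#' corresponds to one WHO-UMC category definition:
#'
#' 1. information insufficient or contradictory — `unassessable`;
#' 2. more data needed — `conditional`;
#' 3. time relationship unknown — `unassessable`;
#' 4. time relationship improbable — `unlikely`;
#' 5. plausible timing, alternatives excluded, positive dechallenge, and the
#'    event pharmacologically definitive or a positive rechallenge —
#'    `certain`;
#' 6. plausible or reasonable timing, alternatives excluded, positive
#'    dechallenge — `probable`;
#' 7. otherwise — `possible`.
#'
#' Only `certain` and `probable` events are counted as adverse drug events.
#'
#' @param evidence A [causality_evidence()].
#' @return One of `"certain"`, `"probable"`, `"possible"`, `"unlikely"`,
#'   `"conditional"`, `"unassessable"`.
#' @export
assess_causality <- function(evidence) {
  e <- evidence
  if (e$information_quality == "insufficient_or_contradictory") return("unassessable")
  if (e$information_quality == "more_data_needed") return("conditional")
  if (e$time_relationship == "unknown") return("unassessable")
  if (e$time_relationship == "improbable") return("unlikely")
  if (e$time_relationship == "plausible" &&
      e$alternative_explanation == "excluded" &&
      e$dechallenge == "positive" &&
      (e$pharmacologically_definitive || e$rechallenge == "positive")) {
    return("certain")
  }
  if (e$time_relationship %in% c("plausible", "reasonable") &&
      e$alternative_explanation == "excluded" &&
      e$dechallenge == "positive") {
    return("probable")
  }
  "possible"
}

#' CTCAE v5 severity grading
#'
#' Precedence cascade over the reviewer's severity findings: death-related
#' events are grade 5; life-threatening events requiring urgent intervention
#' grade 4; events causing or prolonging hospitalization, or disabling /
#' limiting self-care activities of daily living, grade 3; events needing
#' moderate local intervention or limiting instrumental activities of daily
#' living grade 2; all remaining (mild, observation only) grade 1. The
#' grading is monotone: setting any flag never lowers the grade.
#'
#' @param death_related,life_threatening_urgent_intervention,hospitalization_caused_or_prolonged,disabling_or_self_care_adl_limited,moderate_intervention_or_instrumental_adl_limited
#'   Logical severity findings.
#' @return Integer grade 1-5.
#' @export
grade_severity <- function(death_related = FALSE,
                           life_threatening_urgent_intervention = FALSE,
                           hospitalization_caused_or_prolonged = FALSE,
                           disabling_or_self_care_adl_limited = FALSE,
                           moderate_intervention_or_instrumental_adl_limited = FALSE) {
  if (isTRUE(death_related)) return(5L)
  if (isTRUE(life_threatening_urgent_intervention)) return(4L)
  if (isTRUE(hospitalization_caused_or_prolonged) ||
      isTRUE(disabling_or_self_care_adl_limited)) return(3L)
  if (isTRUE(moderate_intervention_or_instrumental_adl_limited)) return(2L)
  1L
}

#' Organ-class map for adjudicated events
#'
#' Static mapping from the primary finding (an event code, or a laboratory
#' analyte for purely biochemical events) to the organ class reported in ADE
#' summaries.
#'
#' @return Named character vector: finding code -> organ class.
#' @export
organ_class_map <- function() {
  c(bp_elevated = "cardiovascular", hypotension_fall = "cardiovascular",
    tachycardia_arrhythmia = "cardiovascular", thromboembolism = "cardiovascular",
    gi_discomfort = "gastrointestinal", drug_induced_vomiting = "gastrointestinal",
    drug_induced_constipation = "gastrointestinal",
    drug_induced_diarrhea = "gastrointestinal",
    weak_contraction_pph = "female_reproductive",
    uterine_hyperstimulation = "female_reproductive",
    vaginal_discomfort = "female_reproductive",
    amniotic_fluid_abnormal = "female_reproductive",
    neonatal_compromise = "fetal_neonatal", neonatal_withdrawal = "fetal_neonatal",
    skin_allergic_reaction = "dermatologic", rash = "dermatologic",
    anaphylaxis = "dermatologic",
    neuro_symptom = "nervous_system", opioid_poisoning = "nervous_system",
    bleeding = "hematologic",
    severe_hypoglycemia_event = "endocrine_metabolic",
    fever_chills = "other", edema = "other", icu_admission_rescue = "other",
    abrupt_med_stop_event = "other",
    # laboratory analytes
    WBC = "hematologic", neutrophils = "hematologic", platelets = "hematologic",
    ALT = "hepatic", ALP = "hepatic", SCr = "renal",
    K = "endocrine_metabolic", Na = "endocrine_metabolic",
    Mg = "endocrine_metabolic", BG_fasting = "endocrine_metabolic",
    BG_postprandial_1h = "endocrine_metabolic",
    BG_postprandial_2h = "endocrine_metabolic",
    TSH = "endocrine_metabolic", TT4 = "endocrine_metabolic",
    FT4 = "endocrine_metabolic", TPOAb = "endocrine_metabolic",
    PT = "hematologic", APTT = "hematologic", INR = "hematologic")
}

#' Build an assessment table
#'
#' One row per reviewed candidate ADE. `event_ids` lists the finding ids
#' (clinical events and/or laboratory results) that constitute the event,
#' primary finding first; `implicated_exposure_ids` the suspected drugs.
#'
#' @param record_id,event_ids,implicated_exposure_ids Identifiers
#'   (`event_ids` / `implicated_exposure_ids` as list columns or
#'   `;`-separated strings).
#' @param causality A [causality_evidence()].
#' @param severity Named logical list with any of the [grade_severity()]
#'   arguments.
#' @return A one-row tibble; rows are combined with [dplyr::bind_rows()].
#' @export
assessment_row <- function(record_id, event_ids, implicated_exposure_ids,
                           causality, severity = list()) {
  sev <- utils::modifyList(
    list(death_related = FALSE, life_threatening_urgent_intervention = FALSE,
         hospitalization_caused_or_prolonged = FALSE,
         disabling_or_self_care_adl_limited = FALSE,
         moderate_intervention_or_instrumental_adl_limited = FALSE),
    severity)
  tibble::tibble(
    record_id = record_id,
    event_ids = list(as.character(event_ids)),
    implicated_exposure_ids = list(as.character(implicated_exposure_ids)),
    time_relationship = causality$time_relationship,
    alternative_explanation = causality$alternative_explanation,
    dechallenge = causality$dechallenge,
    rechallenge = causality$rechallenge,
    pharmacologically_definitive = causality$pharmacologically_definitive,
    information_quality = causality$information_quality,
    death_related = sev$death_related,
    life_threatening_urgent_intervention = sev$life_threatening_urgent_intervention,
    hospitalization_caused_or_prolonged = sev$hospitalization_caused_or_prolonged,
    disabling_or_self_care_adl_limited = sev$disabling_or_self_care_adl_limited,
    moderate_intervention_or_instrumental_adl_limited =
      sev$moderate_intervention_or_instrumental_adl_limited
  )
}

record_finding_ids <- function(rec) {
  c(vapply(rec$labs, `[[`, "", "lab_id"),
    vapply(rec$exposures, `[[`, "", "exposure_id"),
    vapply(rec$events, `[[`, "", "event_id"),
    vapply(rec$neonate_events, `[[`, "", "event_id"))
}

finding_code <- function(rec, id) {
  for (ev in c(rec$events, rec$neonate_events)) {
    if (ev$event_id == id) return(ev$code)
  }
  for (lab in rec$labs) {
    if (lab$lab_id == id) return(lab$analyte)
  }
  NA_character_
}

hit_links_ade <- function(hits, i, ev_ids, impl_ids) {
  length(intersect(hits$evidence_ids[[i]], c(ev_ids, impl_ids))) > 0
}

#' Consolidate trigger hits and assessments into adjudicated ADEs
#'
#' Each assessed clinical event whose WHO-UMC category is `certain` or
#' `probable` yields exactly one ADE record, however many triggers hit it
#' (many hits, one event). An ADE is detected by a method when at least one
#' of that method's hits references it: a hit is linked when its evidence
#' ids intersect the event's finding trail (`event_ids` — the clinical
#' events, laboratory abnormalities and treatment exposures the reviewer
#' tied to the event) or its implicated exposures, within the same record.
#' SRS detection comes
#' from the record's reported-event-id set. An ADE no trigger reached is
#' retained with whatever detection flags remain.
#'
#' @param cohort The screened cohort.
#' @param assessments Assessment tibble ([assessment_row()] /
#'   [read_assessments_csv()]).
#' @param hits Obstetric-registry hit table from [screen_cohort()].
#' @param gtt_hits Optional comparator hit table.
#' @return A tibble with one row per ADE: `ade_id`, `record_id`, `event_ids`,
#'   `implicated_exposure_ids` (list columns), `causality`, `grade`,
#'   `organ_class`, `detected_obstetric`, `detected_gtt`, `detected_srs`.
#' @export
consolidate_ades <- function(cohort, assessments, hits, gtt_hits = NULL) {
  if (is.null(assessments) || nrow(assessments) == 0) {
    return(tibble::tibble(ade_id = character(), record_id = character(),
                          event_ids = list(), implicated_exposure_ids = list(),
                          causality = character(), grade = integer(),
                          organ_class = character(),
                          detected_obstetric = logical(),
                          detected_gtt = logical(), detected_srs = logical()))
  }
  recs <- stats::setNames(cohort, vapply(cohort, `[[`, "", "record_id"))
  omap <- organ_class_map()
  rows <- vector("list", nrow(assessments))
  n_ade <- 0L
  for (i in seq_len(nrow(assessments))) {
    a <- assessments[i, ]
    rec <- recs[[a$record_id]]
    if (is.null(rec)) {
      stop("assessment references unknown record: ", a$record_id, call. = FALSE)
    }
    ev_ids <- a$event_ids[[1]]
    impl <- a$implicated_exposure_ids[[1]]
    known <- record_finding_ids(rec)
    bad <- setdiff(c(ev_ids, impl), known)
    if (length(bad)) {
      stop(sprintf("assessment for record '%s' references unknown finding '%s'",
                   a$record_id, bad[[1]]), call. = FALSE)
    }
    cat_ <- assess_causality(causality_evidence(
      a$time_relationship, a$alternative_explanation, a$dechallenge,
      a$rechallenge, a$pharmacologically_definitive, a$information_quality))
    if (!cat_ %in% c("certain", "probable")) next
    n_ade <- n_ade + 1L
    grade <- grade_severity(a$death_related,
                            a$life_threatening_urgent_intervention,
                            a$hospitalization_caused_or_prolonged,
                            a$disabling_or_self_care_adl_limited,
                            a$moderate_intervention_or_instrumental_adl_limited)
    code <- finding_code(rec, ev_ids[[1]])
    organ <- if (!is.na(code) && code %in% names(omap)) omap[[code]] else "other"
    link_any <- function(h) {
      if (is.null(h) || !nrow(h)) return(FALSE)
      sel <- which(h$record_id == a$record_id)
      any(vapply(sel, function(j) hit_links_ade(h, j, ev_ids, impl), FALSE))
    }
    rows[[n_ade]] <- tibble::tibble(
      ade_id = sprintf("ADE%03d", n_ade),
      record_id = a$record_id,
      event_ids = list(ev_ids),
      implicated_exposure_ids = list(impl),
      causality = cat_, grade = grade, organ_class = organ,
      detected_obstetric = link_any(hits),
      detected_gtt = link_any(gtt_hits),
      detected_srs = length(intersect(ev_ids, rec$srs_reported_event_ids)) > 0
    )
  }
  dplyr::bind_rows(rows[seq_len(n_ade)])
}

#' Flag the hits linked to an adjudicated ADE
#'
#' @param hits A hit table.
#' @param ades Output of [consolidate_ades()].
#' @return Logical vector along the rows of `hits`: TRUE when the hit shares
#'   a finding with some ADE in the same record.
#' @export
ade_flagged_hits <- function(hits, ades) {
  if (!nrow(hits)) return(logical())
  vapply(seq_len(nrow(hits)), function(i) {
    sel <- which(ades$record_id == hits$record_id[i])
    any(vapply(sel, function(j) {
      hit_links_ade(hits, i, ades$event_ids[[j]],
                    ades$implicated_exposure_ids[[j]])
    }, FALSE))
  }, FALSE)
}

#' Read / write assessments as CSV
#'
#' Flat interchange form of the assessment table: `event_ids` and
#' `implicated_exposure_ids` are `;`-separated, severity columns 0/1.
#'
#' @param path CSV path.
#' @return [read_assessments_csv()] returns the assessment tibble.
#' @export
read_assessments_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split_semi <- function(s) {
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1]]
  }
  dplyr::bind_rows(lapply(seq_len(nrow(df)), function(i) {
    assessment_row(
      df$record_id[i], split_semi(df$event_ids[i]),
      split_semi(df$implicated_exposure_ids[i]),
      causality_evidence(df$time_relationship[i],
                         df$alternative_explanation[i], df$dechallenge[i],
                         df$rechallenge[i],
                         df$pharmacologically_definitive[i] == 1,
                         df$information_quality[i]),
      list(death_related = df$death_related[i] == 1,
           life_threatening_urgent_intervention =
             df$life_threatening_urgent_intervention[i] == 1,
           hospitalization_caused_or_prolonged =
             df$hospitalization_caused_or_prolonged[i] == 1,
           disabling_or_self_care_adl_limited =
             df$disabling_or_self_care_adl_limited[i] == 1,
           moderate_intervention_or_instrumental_adl_limited =
             df$moderate_intervention_or_instrumental_adl_limited[i] == 1)
    )
  }))
}

#' @rdname read_assessments_csv
#' @param assessments Assessment tibble.
#' @export
write_assessments_csv <- function(assessments, path) {
  df <- as.data.frame(assessments)
  df$event_ids <- vapply(assessments$event_ids, paste, "", collapse = ";")
  df$implicated_exposure_ids <- vapply(assessments$implicated_exposure_ids,
                                       paste, "", collapse = ";")
  logicals <- vapply(df, is.logical, FALSE)
  df[logicals] <- lapply(df[logicals], as.integer)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export an ADE table to CSV
#' @param ades ADE tibble from [consolidate_ades()].
#' @param path Output path.
#' @export
write_ades_csv <- function(ades, path) {
  df <- as.data.frame(ades)
  df$event_ids <- vapply(ades$event_ids, paste, "", collapse = ";")
  df$implicated_exposure_ids <- vapply(ades$implicated_exposure_ids, paste, "",
                                       collapse = ";")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
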