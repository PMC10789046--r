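# Cohort data model: one obstetric admission per record.
#
# Timestamps are hours since admission (record-local); length of stay in days
# is (discharge_time - admission_time) / 24. All ids (labs, exposures, events,
# neonate events) are unique within a record.

#' Construct a patient record
#'
#' Builds a validated single-admission record. Lists of labs, exposures and
#' events are created with [lab_result()], [medication_exposure()] and
#' [clinical_event()].
#'
#' @param record_id Opaque identifier.
#' @param age Age in completed years.
#' @param gestational_age Gestational age in weeks.
#' @param admission_time,discharge_time Hours since admission epoch;
#'   `discharge_time` must exceed `admission_time`.
#' @param delivery_mode One of `"cesarean"`, `"vaginal"`,
#'   `"fetal_preservation"`, `"none"`.
#' @param diabetic_status `"none"` or `"gestational_or_pregestational"`.
#' @param comorbidity_flags Character vector of controlled exclusion flags.
#' @param labs,exposures,events,neonate_events Lists of component objects.
#' @param srs_reported_event_ids Event ids reported to the spontaneous
#'   reporting system.
#' @param alt_uln,alp_uln Record-level upper limits of normal for ALT/ALP
#'   (U/L) used by the liver-injury rule.
#' @return A list of class `patient_record`.
#' @export
patient_record <- function(record_id, age, gestational_age,
                           admission_time = 0, discharge_time,
                           delivery_mode = "none",
                           diabetic_status = "none",
                           comorbidity_flags = character(),
                           labs = list(), exposures = list(),
                           events = list(), neonate_events = list(),
                           srs_reported_event_ids = character(),
                           alt_uln = 40, alp_uln = 150) {
  rec <- structure(list(
    record_id = as.character(record_id),
    age = as.numeric(age),
    gestational_age = as.numeric(gestational_age),
    admission_time = as.numeric(admission_time),
    discharge_time = as.numeric(discharge_time),
    delivery_mode = delivery_mode,
    diabetic_status = diabetic_status,
    comorbidity_flags = as.character(comorbidity_flags),
    labs = labs,
    exposures = exposures,
    events = events,
    neonate_events = neonate_events,
    srs_reported_event_ids = as.character(srs_reported_event_ids),
    alt_uln = as.numeric(alt_uln),
    alp_uln = as.numeric(alp_uln)
  ), class = "patient_record")
  validate_record(rec)
  rec
}

#' @rdname patient_record
#' @param lab_id,analyte,value,unit,time,is_baseline Laboratory result fields;
#'   `analyte` and `unit` are checked against [analyte_registry()].
#' @export
lab_result <- function(lab_id, analyte, value, unit, time, is_baseline = FALSE) {
  list(lab_id = as.character(lab_id), analyte = analyte,
       value = as.numeric(value), unit = unit, time = as.numeric(time),
       is_baseline = isTRUE(is_baseline))
}

#' @rdname patient_record
#' @param exposure_id,drug_name,drug_classes,start_time,stop_time,abrupt_stop,route
#'   Medication exposure fields; `drug_classes` must be non-empty and drawn
#'   from [drug_class_vocabulary()].
#' @export
medication_exposure <- function(exposure_id, drug_name, drug_classes,
                                start_time, stop_time, abrupt_stop = FALSE,
                                route = "other") {
  list(exposure_id = as.character(exposure_id), drug_name = drug_name,
       drug_classes = as.character(drug_classes),
       start_time = as.numeric(start_time), stop_time = as.numeric(stop_time),
       abrupt_stop = isTRUE(abrupt_stop), route = route)
}

#' @rdname patient_record
#' @param event_id,code,attributes,exclusion_flags Clinical event fields;
#'   `code` must be in [event_vocabulary()]; `attributes` is a named numeric
#'   list (for example `list(SBP = 150)`).
#' @export
clinical_event <- function(event_id, code, time, attributes = list(),
                           exclusion_flags = character()) {
  list(event_id = as.character(event_id), code = code,
       time = as.numeric(time), attributes = attributes,
       exclusion_flags = as.character(exclusion_flags))
}

record_error <- function(record_id, field, msg) {
  stop(sprintf("record '%s', field '%s': %s", record_id, field, msg),
       call. = FALSE)
}

#' Validate a patient record
#'
#' Checks structural invariants: time ordering, enum membership, unit
#' whitelists, id uniqueness, non-empty drug classes, finite lab values.
#' Errors name the record, field and violated constraint.
#'
#' @param rec A `patient_record`.
#' @return The record, invisibly, if valid.
#' @export
validate_record <- function(rec) {
  id <- rec$record_id
  if (!nzchar(id)) stop("record_id must be non-empty", call. = FALSE)
  if (!is.finite(rec$discharge_time) || !is.finite(rec$admission_time) ||
      rec$discharge_time <= rec$admission_time) {
    record_error(id, "discharge_time", "discharge_time must exceed admission_time")
  }
  if (!rec$delivery_mode %in% .delivery_modes) {
    record_error(id, "delivery_mode", paste("unknown value", rec$delivery_mode))
  }
  if (!rec$diabetic_status %in% .diabetic_statuses) {
    record_error(id, "diabetic_status", paste("unknown value", rec$diabetic_status))
  }
  bad_flag <- setdiff(rec$comorbidity_flags, exclusion_flag_vocabulary())
  if (length(bad_flag)) {
    record_error(id, "comorbidity_flags", paste("unknown flag", bad_flag[[1]]))
  }
  for (lab in rec$labs) {
    spec <- .analytes[[lab$analyte]]
    if (is.null(spec)) record_error(id, "labs", paste("unknown analyte", lab$analyte))
    if (!lab$unit %in% spec$allowed) {
      record_error(id, "labs", sprintf("unit '%s' not allowed for analyte %s",
                                       lab$unit, lab$analyte))
    }
    if (!is.finite(lab$value)) {
      record_error(id, "labs", paste("non-finite value for", lab$analyte))
    }
  }
  for (ex in rec$exposures) {
    if (!length(ex$drug_classes)) {
      record_error(id, "exposures", paste("empty drug_classes for", ex$exposure_id))
    }
    bad <- setdiff(ex$drug_classes, drug_class_vocabulary())
    if (length(bad)) record_error(id, "exposures", paste("unknown drug class", bad[[1]]))
    if (ex$stop_time < ex$start_time) {
      record_error(id, "exposures", paste("stop_time before start_time for", ex$exposure_id))
    }
    if (!ex$route %in% .routes) {
      record_error(id, "exposures", paste("unknown route", ex$route))
    }
  }
  for (ev in c(rec$events, rec$neonate_events)) {
    if (!ev$code %in% event_vocabulary()) {
      record_error(id, "events", paste("unknown event code", ev$code))
    }
    bad <- setdiff(ev$exclusion_flags, exclusion_flag_vocabulary())
    if (length(bad)) record_error(id, "events", paste("unknown exclusion flag", bad[[1]]))
  }
  ids <- c(vapply(rec$labs, `[[`, "", "lab_id"),
           vapply(rec$exposures, `[[`, "", "exposure_id"),
           vapply(rec$events, `[[`, "", "event_id"),
           vapply(rec$neonate_events, `[[`, "", "event_id"))
  dup <- ids[duplicated(ids)]
  if (length(dup)) record_error(id, "ids", paste("duplicate id", dup[[1]]))
  missing_srs <- setdiff(rec$srs_reported_event_ids, ids)
  if (length(missing_srs)) {
    record_error(id, "srs_reported_event_ids", paste("unknown id", missing_srs[[1]]))
  }
  invisible(rec)
}

#' Length of stay in days
#' @param rec A `patient_record`.
#' @return Numeric days.
#' @export
length_of_stay <- function(rec) {
  (rec$discharge_time - rec$admission_time) / 24
}

# ---- JSON Lines serialization -------------------------------------------

record_to_list <- function(rec) {
  unclass(rec)
}

record_from_list <- function(x) {
  need <- c("record_id", "age", "gestational_age", "admission_time",
            "discharge_time", "delivery_mode", "diabetic_status")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(sprintf("record '%s': missing field '%s'",
                 if (is.null(x$record_id)) "?" else x$record_id, miss[[1]]),
         call. = FALSE)
  }
  as_chr <- function(v) if (is.null(v) || !length(v)) character() else unlist(v, use.names = FALSE)
  patient_record(
    record_id = x$record_id, age = x$age, gestational_age = x$gestational_age,
    admission_time = x$admission_time, discharge_time = x$discharge_time,
    delivery_mode = x$delivery_mode, diabetic_status = x$diabetic_status,
    comorbidity_flags = as_chr(x$comorbidity_flags),
    labs = lapply(x$labs, function(l) lab_result(
      l$lab_id, l$analyte, l$value, l$unit, l$time, isTRUE(l$is_baseline))),
    exposures = lapply(x$exposures, function(e) medication_exposure(
      e$exposure_id, e$drug_name, as_chr(e$drug_classes), e$start_time,
      e$stop_time, isTRUE(e$abrupt_stop), if (is.null(e$route)) "other" else e$route)),
    events = lapply(x$events, function(ev) clinical_event(
      ev$event_id, ev$code, ev$time,
      if (is.null(ev$attributes)) list() else ev$attributes,
      as_chr(ev$exclusion_flags))),
    neonate_events = lapply(x$neonate_events, function(ev) clinical_event(
      ev$event_id, ev$code, ev$time,
      if (is.null(ev$attributes)) list() else ev$attributes,
      as_chr(ev$exclusion_flags))),
    srs_reported_event_ids = as_chr(x$srs_reported_event_ids),
    alt_uln = if (is.null(x$alt_uln)) 40 else x$alt_uln,
    alp_uln = if (is.null(x$alp_uln)) 150 else x$alp_uln
  )
}

#' Read a cohort from a JSON-Lines file
#'
#' One record object per line, UTF-8. Each record is validated on read;
#' malformed lines are reported with their line number.
#'
#' @param path Path to a `.jsonl` cohort file.
#' @return A list of `patient_record` objects (class `patient_cohort`),
#'   preserving file order.
#' @seealso [write_cohort()], [cohort_from_csv()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    x <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                  error = function(e) {
                    stop(sprintf("line %d: invalid JSON (%s)", i, conditionMessage(e)),
                         call. = FALSE)
                  })
    recs[[i]] <- tryCatch(record_from_list(x), error = function(e) {
      stop(sprintf("line %d: %s", i, conditionMessage(e)), call. = FALSE)
    })
  }
  as_cohort(recs)
}

#' @rdname read_cohort
#' @param cohort A list of `patient_record`s.
#' @export
write_cohort <- function(cohort, path) {
  lines <- vapply(cohort, function(rec) {
    jsonlite::toJSON(record_to_list(rec), auto_unbox = TRUE, digits = NA,
                     null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

as_cohort <- function(recs) {
  structure(recs, class = "patient_cohort")
}

#' @export
print.patient_cohort <- function(x, ...) {
  cat(sprintf("<patient_cohort> %d records\n", length(x)))
  invisible(x)
}

#' Apply the study's record inclusion filter
#'
#' Retains records with gestational age >= 28 weeks, maternal age 16-65
#' years, hospital stay strictly longer than 48 h, and at least one
#' medication exposure. This is a filter, not validation: rejected records
#' are returned with per-record reasons.
#'
#' @param cohort List of validated `patient_record`s.
#' @return A list with `records` (the kept cohort) and `exclusions` (a tibble
#'   of `record_id`, `reason`).
#' @export
apply_inclusion_criteria <- function(cohort) {
  reasons <- lapply(cohort, function(rec) {
    r <- character()
    if (rec$gestational_age < 28) r <- c(r, "gestational age < 28 weeks")
    if (rec$age < 16 || rec$age > 65) r <- c(r, "age outside 16-65")
    if (length_of_stay(rec) <= 2) r <- c(r, "stay <= 48h")
    if (!length(rec$exposures)) r <- c(r, "no medication records")
    r
  })
  keep <- lengths(reasons) == 0
  excl <- tibble::tibble(
    record_id = vapply(cohort[!keep], `[[`, "", "record_id"),
    reason = vapply(reasons[!keep], paste, "", collapse = "; ")
  )
  list(records = as_cohort(cohort[keep]), exclusions = excl)
}

# ---- CSV ingestion -------------------------------------------------------

#' Assemble a cohort from tabular CSV inputs
#'
#' Secondary ingestion path: four CSV files keyed by `record_id` —
#' `patients.csv` (demographics and stay), `labs.csv`, `exposures.csv`
#' (drug classes `;`-separated) and `events.csv` (attributes as
#' `key=value;key=value`, `is_neonate` 0/1). Produces the same validated
#' records as [read_cohort()].
#'
#' @param patients,labs,exposures,events Paths to the four CSV files;
#'   `labs`, `exposures` and `events` may be `NULL`.
#' @return A `patient_cohort`.
#' @export
cohort_from_csv <- function(patients, labs = NULL, exposures = NULL,
                            events = NULL) {
  pat <- utils::read.csv(patients, stringsAsFactors = FALSE)
  lab_df <- if (!is.null(labs)) utils::read.csv(labs, stringsAsFactors = FALSE) else NULL
  exp_df <- if (!is.null(exposures)) utils::read.csv(exposures, stringsAsFactors = FALSE) else NULL
  ev_df <- if (!is.null(events)) utils::read.csv(events, stringsAsFactors = FALSE) else NULL
  split_semi <- function(s) if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1]]
  parse_attrs <- function(s) {
    parts <- split_semi(s)
    if (!length(parts)) return(list())
    kv <- strsplit(parts, "=", fixed = TRUE)
    stats::setNames(lapply(kv, function(p) as.numeric(p[[2]])),
                    vapply(kv, `[[`, "", 1))
  }
  recs <- lapply(seq_len(nrow(pat)), function(i) {
    p <- pat[i, ]
    rid <- as.character(p$record_id)
    l <- if (!is.null(lab_df)) lab_df[lab_df$record_id == rid, , drop = FALSE] else NULL
    e <- if (!is.null(exp_df)) exp_df[exp_df$record_id == rid, , drop = FALSE] else NULL
    v <- if (!is.null(ev_df)) ev_df[ev_df$record_id == rid, , drop = FALSE] else NULL
    evs <- list(); nevs <- list()
    if (!is.null(v) && nrow(v)) {
      for (j in seq_len(nrow(v))) {
        ev <- clinical_event(v$event_id[j], v$code[j], v$time[j],
                             parse_attrs(if ("attributes" %in% names(v)) v$attributes[j] else ""),
                             split_semi(if ("exclusion_flags" %in% names(v)) v$exclusion_flags[j] else ""))
        if ("is_neonate" %in% names(v) && isTRUE(v$is_neonate[j] == 1)) {
          nevs <- c(nevs, list(ev))
        } else {
          evs <- c(evs, list(ev))
        }
      }
    }
    patient_record(
      record_id = rid, age = p$age, gestational_age = p$gestational_age,
      admission_time = p$admission_time, discharge_time = p$discharge_time,
      delivery_mode = p$delivery_mode, diabetic_status = p$diabetic_status,
      comorbidity_flags = split_semi(if ("comorbidity_flags" %in% names(p)) p$comorbidity_flags else ""),
      labs = if (!is.null(l) && nrow(l)) lapply(seq_len(nrow(l)), function(j) {
        lab_result(l$lab_id[j], l$analyte[j], l$value[j], l$unit[j], l$time[j],
                   if ("is_baseline" %in% names(l)) isTRUE(l$is_baseline[j] == 1) else FALSE)
      }) else list(),
      exposures = if (!is.null(e) && nrow(e)) lapply(seq_len(nrow(e)), function(j) {
        medication_exposure(e$exposure_id[j], e$drug_name[j],
                            split_semi(e$drug_classes[j]), e$start_time[j],
                            e$stop_time[j],
                            if ("abrupt_stop" %in% names(e)) isTRUE(e$abrupt_stop[j] == 1) else FALSE,
                            if ("route" %in% names(e)) e$route[j] else "other")
      }) else list(),
      events = evs, neonate_events = nevs,
      srs_reported_event_ids = split_semi(if ("srs_reported_event_ids" %in% names(p)) p$srs_reported_event_ids else "")
    )
  })
  as_cohort(recs)
}

#' Summarise a cohort as a tibble
#'
#' One row per record with demographics, stay and component counts; a
#' convenience view for exploration, not the serialized form.
#'
#' @param cohort A `patient_cohort`.
#' @return A tibble.
#' @export
cohort_tibble <- function(cohort) {
  tibble::tibble(
    record_id = vapply(cohort, `[[`, "", "record_id"),
    age = vapply(cohort, `[[`, 0, "age"),
    gestational_age = vapply(cohort, `[[`, 0, "gestational_age"),
    length_of_stay = vapply(cohort, length_of_stay, 0),
    delivery_mode = vapply(cohort, `[[`, "", "delivery_mode"),
    diabetic_status = vapply(cohort, `[[`, "", "diabetic_status"),
    n_labs = lengths(lapply(cohort, `[[`, "labs")),
    n_exposures = lengths(lapply(cohort, `[[`, "exposures")),
    n_events = lengths(lapply(cohort, `[[`, "events")) +
      lengths(lapply(cohort, `[[`, "neonate_events"))
  )
}
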