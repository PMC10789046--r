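# Stochastic synthetic cohort generator with known ground truth.
#
# Each trigger has a planting recipe: the minimal set of findings that makes
# exactly that trigger fire (plus, where the comparator reads the same
# finding, the corresponding GTT rule). Defaults reproduce the study
# conditions: 300 records, age centred on 27.45 years (range 18-43), stays
# drawn from the integer histogram behind the 4.34-day mean, the observed
# delivery mix, and per-trigger firing / conditional-ADE probabilities equal
# to the observed per-trigger rates.

#' Observed per-trigger count structure of the study review
#'
#' Positive-trigger and ADE counts per trigger over the 300-record review;
#' used as the generator's default firing and conditional-ADE rates.
#'
#' @return Tibble: `trigger_id`, `module`, `positives`, `ades`.
#' @export
study_trigger_counts <- function() {
  tibble::tibble(
    trigger_id = c("L1", "L2", "L3", "L4", "L5", "L6", "L7", "L8", "L9",
                   "L10", "L11", "L12",
                   "M1", "M2", "M3", "M4", "M5", "M6", "M7", "M8", "M9",
                   "S1", "S2", "S3", "S4", "S5", "S6", "S7", "S8", "S9",
                   "S10", "S11", "S12", "S13", "S14",
                   "O1", "O2", "O3", "O4"),
    module = rep(c("laboratory", "medication", "symptom", "outcome"),
                 times = c(12, 9, 14, 4)),
    positives = c(1, 0, 0, 0, 17, 4, 0, 0, 3, 1, 2, 7,
                  0, 1, 0, 0, 0, 36, 0, 1, 15,
                  3, 10, 11, 0, 4, 7, 0, 0, 0, 2, 9, 0, 4, 0,
                  2, 3, 11, 0),
    ades = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0,
             0, 1, 0, 0, 0, 2, 0, 1, 0,
             2, 6, 11, 0, 3, 5, 0, 0, 0, 2, 9, 0, 4, 0,
             2, 0, 7, 0)
  )
}

#' Simulation parameters
#'
#' @param n_records Cohort size.
#' @param firing_prob Named per-trigger probability that a record carries the
#'   trigger's planted finding; defaults to the observed positive rates
#'   (positives / 300).
#' @param ade_prob Named per-trigger probability that a planted finding is a
#'   true ADE (reviewed as causally related); defaults to the observed
#'   per-trigger PPVs. Must be zero wherever `firing_prob` is zero.
#' @param age_mean,age_sd,age_range Maternal age distribution (years).
#' @param stay_days,stay_weights Integer length-of-stay support and weights.
#' @param delivery_probs Named probabilities for cesarean / vaginal /
#'   fetal_preservation.
#' @param severity_probs Probabilities of CTCAE grades 1-5 for a planted ADE.
#' @param srs_prob Probability that a true ADE was also reported to the
#'   spontaneous reporting system.
#' @param risk_model Optional list `(intercept, coefs)` — named log-odds for
#'   the record-level ADE outcome used by risk-factor simulations; when set,
#'   ADEs are generated from the logistic model instead of per-trigger
#'   conditional probabilities.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_records = 300,
                       firing_prob = NULL,
                       ade_prob = NULL,
                       age_mean = 27.45, age_sd = 4.5, age_range = c(18, 43),
                       stay_days = 3:10,
                       stay_weights = c(68, 145, 48, 18, 9, 5, 4, 3),
                       delivery_probs = c(cesarean = 115, vaginal = 162,
                                          fetal_preservation = 23) / 300,
                       severity_probs = c(17, 27, 5, 0, 0) / 49,
                       srs_prob = 7 / 49,
                       risk_model = NULL) {
  counts <- study_trigger_counts()
  if (is.null(firing_prob)) {
    firing_prob <- stats::setNames(counts$positives / 300, counts$trigger_id)
  }
  if (is.null(ade_prob)) {
    ade_prob <- stats::setNames(
      ifelse(counts$positives > 0, counts$ades / pmax(counts$positives, 1), 0),
      counts$trigger_id)
  }
  missing_p <- setdiff(counts$trigger_id, names(firing_prob))
  if (length(missing_p)) firing_prob[missing_p] <- 0
  missing_a <- setdiff(counts$trigger_id, names(ade_prob))
  if (length(missing_a)) ade_prob[missing_a] <- 0
  if (any(firing_prob < 0 | firing_prob > 1) || any(ade_prob < 0 | ade_prob > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  bad <- names(ade_prob)[ade_prob > 0 & firing_prob[names(ade_prob)] == 0]
  if (length(bad)) {
    stop("conditional ADE probability set for inactive trigger: ", bad[[1]],
         call. = FALSE)
  }
  if (abs(sum(severity_probs) - 1) > 1e-8 || abs(sum(delivery_probs) - 1) > 1e-8) {
    stop("severity_probs and delivery_probs must each sum to 1", call. = FALSE)
  }
  structure(list(n_records = n_records, firing_prob = firing_prob,
                 ade_prob = ade_prob, age_mean = age_mean, age_sd = age_sd,
                 age_range = age_range, stay_days = stay_days,
                 stay_weights = stay_weights, delivery_probs = delivery_probs,
                 severity_probs = severity_probs, srs_prob = srs_prob,
                 risk_model = risk_model),
            class = "sim_params")
}

# planting recipes: findings that make exactly one obstetric trigger fire.
# Each returns list(labs, events, nevents, exps, primary, impl). Ids are
# prefixed by the trigger id so a record can carry several plants.
sim_recipe <- function(tid, t0 = 26) {
  p <- function(s) paste0(tid, "_", s)
  lab1 <- function(analyte, value, unit, dt = 0, base = FALSE) {
    lab_result(p("LB"), analyte, value, unit, t0 + dt, base)
  }
  ev1 <- function(code, attrs = list(), flags = character(), dt = 0) {
    clinical_event(p("E"), code, t0 + dt, attrs, flags)
  }
  ex1 <- function(classes, dt0 = -16, dt1 = -6, route = "other", id = "D",
                  abrupt = FALSE) {
    medication_exposure(p(id), paste0(tid, " drug"), classes, t0 + dt0,
                        t0 + dt1, abrupt, route)
  }
  out <- list(labs = list(), events = list(), nevents = list(), exps = list())
  add <- function(out, what, x) { out[[what]] <- c(out[[what]], list(x)); out }
  switch(tid,
    L1 = { out <- add(out, "labs", lab1("K", 3.1, "mmol/L"))
           out <- add(out, "exps", ex1("hypokalemic")) },
    L2 = { out <- add(out, "labs", lab1("K", 6.0, "mmol/L"))
           out <- add(out, "exps", ex1("hyperkalemic")) },
    L3 = { out <- add(out, "labs", lab1("Mg", 4.0, "mmol/L"))
           out <- add(out, "exps", ex1(c("hypermagnesemic", "magnesium_sulfate"))) },
    L4 = { out <- add(out, "labs", lab1("Na", 125, "mmol/L"))
           out <- add(out, "exps", ex1("hyponatremic")) },
    L5 = { out <- add(out, "labs", lab1("BG_fasting", 2.5, "mmol/L"))
           out <- add(out, "exps", ex1("hypoglycemic")) },
    L6 = { out <- add(out, "labs", lab1("BG_fasting", 7.0, "mmol/L"))
           out <- add(out, "exps", ex1("hyperglycemic")) },
    L7 = { out$labs <- list(lab_result(p("LB1"), "SCr", 0.6, "mg/dL", t0 - 24, TRUE),
                            lab_result(p("LB2"), "SCr", 0.95, "mg/dL", t0))
           out <- add(out, "exps", ex1("nephrotoxic")) },
    L8 = { out <- add(out, "labs", lab1("PT", 15, "s"))
           out <- add(out, "events", ev1("bleeding"))
           out <- add(out, "exps", ex1(c("heparin", "anticoagulant"))) },
    L9 = { out <- add(out, "labs", lab1("platelets", 40, "10^9/L"))
           out <- add(out, "exps", ex1("thrombocytopenic")) },
    L10 = { out <- add(out, "labs", lab1("TSH", 5.0, "mIU/L"))
            out <- add(out, "exps", ex1("antithyroid")) },
    L11 = { out <- add(out, "labs", lab1("WBC", 4.5, "10^9/L"))
            out <- add(out, "exps", ex1("leukopenic")) },
    L12 = { out$labs <- list(lab_result(p("LB1"), "ALT", 150, "U/L", t0),
                             lab_result(p("LB2"), "ALP", 80, "U/L", t0))
            out <- add(out, "exps", ex1("hepatotoxic")) },
    M1 = { out <- add(out, "exps", ex1("heparin"))
           out <- add(out, "exps", ex1("protamine", dt0 = 2, dt1 = 3, id = "D2")) },
    M2 = { out <- add(out, "events", ev1("anaphylaxis"))
           out <- add(out, "exps", ex1("antibiotic"))
           out <- add(out, "exps", ex1("antihistamine", dt0 = 2, dt1 = 3, id = "D2")) },
    M3 = { out <- add(out, "events", ev1("anaphylaxis"))
           out <- add(out, "exps", ex1("antibiotic"))
           out <- add(out, "exps", ex1("adrenaline", dt0 = 2, dt1 = 3, id = "D2")) },
    M4 = { out <- add(out, "events", ev1("severe_hypoglycemia_event"))
           out <- add(out, "exps", ex1(c("hypoglycemic", "insulin")))
           out <- add(out, "exps", ex1("glucose_50pct", dt0 = 2, dt1 = 3, id = "D2")) },
    M5 = { out <- add(out, "events", ev1("opioid_poisoning"))
           out <- add(out, "exps", ex1("opioid_analgesic"))
           out <- add(out, "exps", ex1("naloxone_nalmefene", dt0 = 2, dt1 = 3, id = "D2")) },
    M6 = { out <- add(out, "events", ev1("drug_induced_constipation"))
           out <- add(out, "exps", ex1("opioid_analgesic"))
           out <- add(out, "exps", ex1("laxative", dt0 = 2, dt1 = 3, id = "D2")) },
    M7 = { out <- add(out, "events", ev1("drug_induced_diarrhea"))
           out <- add(out, "exps", ex1("prostaglandin"))
           out <- add(out, "exps", ex1("live_bacteria_antidiarrheal",
                                       dt0 = 2, dt1 = 3, id = "D2")) },
    M8 = { out <- add(out, "events", ev1("drug_induced_vomiting"))
           out <- add(out, "exps", ex1("prostaglandin"))
           out <- add(out, "exps", ex1("antiemetic", dt0 = 2, dt1 = 3, id = "D2")) },
    M9 = { out <- add(out, "exps", ex1("magnesium_sulfate"))
           out <- add(out, "exps", ex1("calcium_gluconate", dt0 = 2, dt1 = 3,
                                       route = "IV", id = "D2")) },
    S1 = { out <- add(out, "events", ev1("skin_allergic_reaction"))
           out <- add(out, "exps", ex1("antibiotic")) },
    S2 = { out <- add(out, "events", ev1("hypotension_fall"))
           out <- add(out, "exps", ex1("magnesium_sulfate")) },
    S3 = { out <- add(out, "events", ev1("bp_elevated", list(SBP = 150, DBP = 92)))
           out <- add(out, "exps", ex1("oxytocin")) },
    S4 = { out <- add(out, "events", ev1("bleeding"))
           out <- add(out, "exps", ex1("NSAID")) },
    S5 = { out <- add(out, "events", ev1("weak_contraction_pph"))
           out <- add(out, "exps", ex1("magnesium_sulfate")) },
    S6 = { out <- add(out, "events", ev1("uterine_hyperstimulation"))
           out <- add(out, "exps", ex1("oxytocin")) },
    S7 = { out <- add(out, "events", ev1("edema"))
           out <- add(out, "exps", ex1("NSAID")) },
    S8 = { out <- add(out, "events", ev1("thromboembolism"))
           out <- add(out, "exps", ex1("glucocorticoid")) },
    S9 = { out <- add(out, "events", ev1("fever_chills", list(temp_rise = 2.5)))
           out <- add(out, "exps", ex1("prostaglandin")) },
    S10 = { out <- add(out, "events", ev1("neuro_symptom"))
            out <- add(out, "exps", ex1("antibiotic")) },
    S11 = { out <- add(out, "events", ev1("gi_discomfort"))
            out <- add(out, "exps", ex1("prostaglandin")) },
    S12 = { out <- add(out, "events", ev1("vaginal_discomfort"))
            out <- add(out, "exps", ex1("vaginal_topical")) },
    S13 = { out <- add(out, "events", ev1("tachycardia_arrhythmia",
                                          list(heart_rate = 150)))
            out <- add(out, "exps", ex1("oxytocin")) },
    S14 = { out <- add(out, "events", ev1("amniotic_fluid_abnormal"))
            out <- add(out, "exps", ex1("oxytocin")) },
    O1 = { out <- add(out, "events", ev1("icu_admission_rescue"))
           out <- add(out, "exps", ex1("magnesium_sulfate")) },
    O2 = { out <- add(out, "events", ev1("abrupt_med_stop_event"))
           out <- add(out, "exps", ex1(c("long_term_maintenance",
                                         "antihypertensive"), dt0 = -24, dt1 = 0)) },
    O3 = { out <- add(out, "nevents", ev1("neonatal_compromise"))
           out <- add(out, "exps", ex1("oxytocin")) },
    O4 = { out <- add(out, "nevents", ev1("neonatal_withdrawal"))
           out <- add(out, "exps", ex1("opioid_analgesic")) },
    stop("no planting recipe for trigger ", tid, call. = FALSE)
  )
  out$primary <- if (length(out$events)) out$events[[1]]$event_id
    else if (length(out$nevents)) out$nevents[[1]]$event_id
    else if (length(out$labs)) out$labs[[length(out$labs)]]$lab_id
    else out$exps[[length(out$exps)]]$exposure_id  # drug-sequence rules
  out$impl <- out$exps[[1]]$exposure_id
  out
}

#' Generate a synthetic cohort with known truth
#'
#' Draws demographics from the study-condition distributions, plants each
#' trigger's finding independently with its firing probability, marks planted
#' findings as true ADEs with the trigger's conditional ADE probability, and
#' builds the matching reviewer assessment table. Reproducible: the same
#' `params` and `seed` give byte-identical output.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed for all randomness.
#' @return A list: `cohort`, `assessments`, `truth` (tibble of planted
#'   findings with `record_id`, `trigger_id`, `is_ade`).
#' @export
generate_cohort <- function(params = sim_params(), seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  n <- params$n_records
  ages <- round(stats::rnorm(n, params$age_mean, params$age_sd))
  ages <- pmin(pmax(ages, params$age_range[1]), params$age_range[2])
  stays <- sample(params$stay_days, n, replace = TRUE,
                  prob = params$stay_weights)
  delivery <- sample(names(params$delivery_probs), n, replace = TRUE,
                     prob = params$delivery_probs)
  trigger_ids <- study_trigger_counts()$trigger_id
  active <- trigger_ids[params$firing_prob[trigger_ids] > 0]

  cohort <- vector("list", n)
  assessments <- list()
  truth <- list()
  rm_cfg <- params$risk_model

  for (i in seq_len(n)) {
    rid <- sprintf("S%05d", i)
    labs <- list(); events <- list(); nevents <- list()
    exps <- list(medication_exposure("BASE", "prenatal vitamins", "other", 2, 4))

    if (is.null(rm_cfg)) {
      fired <- active[stats::runif(length(active)) < params$firing_prob[active]]
      for (tid in fired) {
        rec <- sim_recipe(tid)
        labs <- c(labs, rec$labs); events <- c(events, rec$events)
        nevents <- c(nevents, rec$nevents); exps <- c(exps, rec$exps)
        is_ade <- stats::runif(1) < params$ade_prob[[tid]]
        truth[[length(truth) + 1]] <- tibble::tibble(
          record_id = rid, trigger_id = tid, is_ade = is_ade)
        if (is_ade) {
          grade <- sample(1:5, 1, prob = params$severity_probs)
          assessments[[length(assessments) + 1]] <- assessment_row(
            rid, rec$primary, rec$impl,
            causality_evidence("reasonable", "excluded", dechallenge = "positive"),
            fx_severity(min(grade, 3L)))
        }
      }
    } else {
      # risk-factor mode: covariate-driven record-level ADE outcome
      n_abx <- stats::rpois(1, 0.8)
      n_inj <- stats::rpois(1, 1)
      n_extra <- stats::rpois(1, 1)
      if (n_abx > 0) for (k in seq_len(n_abx)) {
        exps <- c(exps, list(medication_exposure(
          sprintf("ABX%d", k), "antibiotic", "antibiotic", 6, 10, route = "oral")))
      }
      if (n_inj > 0) for (k in seq_len(n_inj)) {
        exps <- c(exps, list(medication_exposure(
          sprintf("INJ%d", k), "injectable", "other", 6, 10, route = "IV")))
      }
      if (n_extra > 0) for (k in seq_len(n_extra)) {
        exps <- c(exps, list(medication_exposure(
          sprintf("EXT%d", k), "oral drug", "other", 6, 10, route = "oral")))
      }
      covs <- c(age = ages[i], length_of_stay = stays[i],
                n_drugs = length(exps), n_antibacterials = n_abx,
                n_injections = n_inj,
                cesarean = as.numeric(delivery[i] == "cesarean"),
                vaginal = as.numeric(delivery[i] == "vaginal"))
      lp <- rm_cfg$intercept + sum(rm_cfg$coefs * covs[names(rm_cfg$coefs)])
      if (stats::runif(1) < stats::plogis(lp)) {
        events <- c(events, list(clinical_event("E_ADE", "gi_discomfort", 26)))
        assessments[[length(assessments) + 1]] <- assessment_row(
          rid, "E_ADE", "BASE",
          causality_evidence("reasonable", "excluded", dechallenge = "positive"),
          list())
        truth[[length(truth) + 1]] <- tibble::tibble(
          record_id = rid, trigger_id = "S11", is_ade = TRUE)
      }
    }

    cohort[[i]] <- patient_record(
      record_id = rid, age = ages[i],
      gestational_age = if (delivery[i] == "fetal_preservation") 32 else 38,
      admission_time = 0, discharge_time = stays[i] * 24,
      delivery_mode = delivery[i], diabetic_status = "none",
      labs = labs, exposures = exps, events = events,
      neonate_events = nevents
    )
  }

  truth_df <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble::tibble(record_id = character(), trigger_id = character(),
                   is_ade = logical())
  assess_df <- if (length(assessments)) dplyr::bind_rows(assessments) else NULL

  # SRS reporting: flag a subset of true-ADE primary findings
  if (!is.null(assess_df) && nrow(assess_df) && params$srs_prob > 0) {
    rep_sel <- stats::runif(nrow(assess_df)) < params$srs_prob
    if (any(rep_sel)) {
      by_rec <- split(which(rep_sel), assess_df$record_id[rep_sel])
      idx_by_id <- stats::setNames(seq_len(n),
                                   vapply(cohort, `[[`, "", "record_id"))
      for (rid in names(by_rec)) {
        j <- idx_by_id[[rid]]
        ids <- vapply(by_rec[[rid]], function(k) assess_df$event_ids[[k]][1], "")
        cohort[[j]]$srs_reported_event_ids <- unique(ids)
      }
    }
  }

  list(cohort = as_cohort(cohort), assessments = assess_df, truth = truth_df)
}
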