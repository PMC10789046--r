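# Controlled vocabularies and laboratory unit handling.
#
# All trigger thresholds are compared in a fixed canonical unit per analyte:
# mmol/L for electrolytes and glucose, mg/dL for creatinine (the convention the
# acute-kidney-injury delta rule is written in), 10^9/L for cell counts,
# seconds for clotting times, U/L for enzymes. Values are converted once, at
# comparison time, using fixed clinical-chemistry factors.

#' Analyte registry
#'
#' Returns the controlled laboratory vocabulary: one row per analyte with its
#' canonical unit and the whitelist of accepted input units.
#'
#' @return A tibble with columns `analyte`, `canonical_unit`, `allowed_units`
#'   (list column).
#' @export
analyte_registry <- function() {
  tibble::tibble(
    analyte = names(.analytes),
    canonical_unit = vapply(.analytes, `[[`, "", "canonical"),
    allowed_units = lapply(.analytes, `[[`, "allowed")
  )
}

.analytes <- list(
  K                 = list(canonical = "mmol/L", allowed = c("mmol/L", "mEq/L")),
  Na                = list(canonical = "mmol/L", allowed = c("mmol/L", "mEq/L")),
  Mg                = list(canonical = "mmol/L", allowed = c("mmol/L")),
  BG_fasting        = list(canonical = "mmol/L", allowed = c("mmol/L", "mg/dL")),
  BG_postprandial_1h = list(canonical = "mmol/L", allowed = c("mmol/L", "mg/dL")),
  BG_postprandial_2h = list(canonical = "mmol/L", allowed = c("mmol/L", "mg/dL")),
  SCr               = list(canonical = "mg/dL", allowed = c("mg/dL", "umol/L")),
  PT                = list(canonical = "s", allowed = c("s")),
  APTT              = list(canonical = "s", allowed = c("s")),
  INR               = list(canonical = "ratio", allowed = c("ratio")),
  platelets         = list(canonical = "10^9/L", allowed = c("10^9/L", "/uL")),
  TSH               = list(canonical = "mIU/L", allowed = c("mIU/L")),
  TT4               = list(canonical = "nmol/L", allowed = c("nmol/L")),
  FT4               = list(canonical = "pmol/L", allowed = c("pmol/L")),
  TPOAb             = list(canonical = "IU/mL", allowed = c("IU/mL")),
  WBC               = list(canonical = "10^9/L", allowed = c("10^9/L", "/uL")),
  neutrophils       = list(canonical = "10^9/L", allowed = c("10^9/L", "/uL")),
  ALT               = list(canonical = "U/L", allowed = c("U/L")),
  ALP               = list(canonical = "U/L", allowed = c("U/L")),
  urine_output_rate = list(canonical = "mL/kg/h", allowed = c("mL/kg/h")),
  body_temperature  = list(canonical = "C", allowed = c("C")),
  heart_rate        = list(canonical = "bpm", allowed = c("bpm")),
  SBP               = list(canonical = "mmHg", allowed = c("mmHg")),
  DBP               = list(canonical = "mmHg", allowed = c("mmHg"))
)

# multiplicative factors: value[to] = value[from] * factor
# glucose molar mass 180.16 g/mol -> 18.016 (mg/dL per mmol/L);
# creatinine 113.12 g/mol -> 88.4 (umol/L per mg/dL).
.unit_factors <- list(
  "mEq/L->mmol/L"  = 1,        # monovalent ions only (K, Na)
  "mmol/L->mEq/L"  = 1,
  "mg/dL->umol/L"  = 88.4,     # creatinine
  "umol/L->mg/dL"  = 1 / 88.4,
  "mg/dL->mmol/L"  = 1 / 18.016,  # glucose
  "mmol/L->mg/dL"  = 18.016,
  "/uL->10^9/L"    = 1e-3,     # cells/uL -> 10^9 cells/L
  "10^9/L->/uL"    = 1e3
)

#' Convert a laboratory value between units
#'
#' Fixed published conversion factors; identity when units are equal. The pair
#' must be in the analyte's allowed unit set.
#'
#' @param value Numeric value.
#' @param analyte Controlled analyte code (see [analyte_registry()]).
#' @param from_unit,to_unit Unit strings.
#' @return The converted numeric value.
#' @examples
#' convert_lab_unit(1.0, "SCr", "mg/dL", "umol/L") # 88.4
#' convert_lab_unit(50, "BG_fasting", "mg/dL", "mmol/L") # 2.775
#' @export
convert_lab_unit <- function(value, analyte, from_unit, to_unit) {
  spec <- .analytes[[analyte]]
  if (is.null(spec)) {
    stop("unknown analyte: ", analyte, call. = FALSE)
  }
  bad <- setdiff(c(from_unit, to_unit), spec$allowed)
  if (length(bad)) {
    stop(sprintf("unit '%s' not allowed for analyte %s (allowed: %s)",
                 bad[[1]], analyte, paste(spec$allowed, collapse = ", ")),
         call. = FALSE)
  }
  if (identical(from_unit, to_unit)) return(value)
  key <- paste0(from_unit, "->", to_unit)
  f <- .unit_factors[[key]]
  if (is.null(f)) {
    stop(sprintf("unsupported unit conversion for %s: %s", analyte, key),
         call. = FALSE)
  }
  value * f
}

# convert to the analyte's canonical unit
to_canonical <- function(value, analyte, unit) {
  convert_lab_unit(value, analyte, unit, .analytes[[analyte]]$canonical)
}

#' Controlled event vocabulary
#'
#' Clinical event codes understood by the symptom/outcome triggers and the
#' medication sequence rules. `rash` is the comparator tool's generic rash
#' clue, distinct from the obstetric allergic-skin-reaction code.
#'
#' @return Character vector of event codes.
#' @export
event_vocabulary <- function() {
  c("skin_allergic_reaction", "hypotension_fall", "bp_elevated", "bleeding",
    "weak_contraction_pph", "uterine_hyperstimulation", "edema",
    "thromboembolism", "fever_chills", "neuro_symptom", "gi_discomfort",
    "vaginal_discomfort", "tachycardia_arrhythmia", "amniotic_fluid_abnormal",
    "icu_admission_rescue", "abrupt_med_stop_event", "neonatal_compromise",
    "neonatal_withdrawal", "anaphylaxis", "severe_hypoglycemia_event",
    "opioid_poisoning", "drug_induced_constipation", "drug_induced_diarrhea",
    "drug_induced_vomiting", "rash")
}

#' Controlled drug class vocabulary
#'
#' Class tags carried by medication exposures and referenced by trigger
#' predicates and suspect-drug queries.
#'
#' @return Character vector of class tags.
#' @export
drug_class_vocabulary <- function() {
  c("hypokalemic", "hyperkalemic", "hypermagnesemic", "hyponatremic",
    "hypoglycemic", "hyperglycemic", "nephrotoxic", "heparin",
    "thrombocytopenic", "antithyroid", "leukopenic", "hepatotoxic",
    "protamine", "glucocorticoid", "antihistamine", "calcium_gluconate",
    "adrenaline", "glucose_50pct", "naloxone_nalmefene", "laxative",
    "live_bacteria_antidiarrheal", "antiemetic", "magnesium_sulfate",
    "oxytocin", "prostaglandin", "ergonovine", "antihypertensive",
    "sedative_hypnotic", "opioid_analgesic", "NSAID", "antibiotic",
    "anticoagulant", "long_term_maintenance", "vaginal_topical",
    "diphenhydramine", "vitamin_k", "flumazenil", "insulin", "other")
}

#' Comorbidity / exclusion flag vocabulary
#'
#' Record- and event-level flags that encode chart-reviewer judgement used by
#' trigger exclusion guards (for example, physiological dilution of platelets
#' in pregnancy, or nausea attributable to morning sickness).
#'
#' @return Character vector of flags.
#' @export
exclusion_flag_vocabulary <- function() {
  c("physiologic_thrombocytopenia", "vaginitis", "infection",
    "preexisting_hypertension_uncontrolled", "PROM", "thyroid_disease",
    "disease_related_cytopenia", "morning_sickness", "disease_explained",
    "spontaneous_pregnancy_embolism", "cord_torsion", "stress_related")
}

.delivery_modes <- c("cesarean", "vaginal", "fetal_preservation", "none")
.diabetic_statuses <- c("none", "gestational_or_pregestational")
.routes <- c("IV", "oral", "vaginal", "IM", "other")
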