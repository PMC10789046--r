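# Built-in trigger registries.
#
# The obstetric registry has four modules: 12 laboratory triggers (L1-L12),
# 9 medication triggers (M1-M9), 14 symptom triggers (S1-S14) and 4 outcome
# triggers (O1-O4). Screening semantics: the left-hand clue (the predicate)
# fires on its own; the drug context becomes the suspect-exposure query
# attached to the hit for adjudication. Inequalities are strict exactly as
# printed (a potassium of 3.3 mmol/L does not fire the "< 3.3" rule).

bg_analytes <- c("BG_fasting", "BG_postprandial_1h", "BG_postprandial_2h")
uterotonics <- c("oxytocin", "prostaglandin", "ergonovine")

#' The 39-item obstetric trigger registry
#'
#' @return A `trigger_registry` with 12 laboratory, 9 medication, 14 symptom
#'   and 4 outcome triggers.
#' @seealso [load_registry()], [gtt_registry()], [revised_registry()]
#' @export
obstetric_registry <- function() {
  t <- list(
    # -- laboratory ------------------------------------------------------
    trigger_def("L1", "laboratory", "K < 3.3 mmol/L",
                pred_lab("K", "<", 3.3, "mmol/L"),
                suspect_classes = "hypokalemic"),
    trigger_def("L2", "laboratory", "K > 5.5 mmol/L",
                pred_lab("K", ">", 5.5, "mmol/L"),
                suspect_classes = "hyperkalemic"),
    trigger_def("L3", "laboratory", "Mg > 3.5 mmol/L",
                pred_lab("Mg", ">", 3.5, "mmol/L"),
                suspect_classes = "hypermagnesemic"),
    trigger_def("L4", "laboratory", "Na < 130 mmol/L",
                pred_lab("Na", "<", 130, "mmol/L"),
                suspect_classes = "hyponatremic"),
    trigger_def("L5", "laboratory",
                "hypoglycemia (BG < 3.3; diabetic on hypoglycemic therapy < 3.9)",
                pred_any(
                  pred_lab(bg_analytes, "<", 3.3, "mmol/L",
                           requires_status = "none"),
                  pred_lab(bg_analytes, "<", 3.9, "mmol/L",
                           requires_status = "gestational_or_pregestational",
                           requires_class = c("hypoglycemic", "insulin"))
                ),
                suspect_classes = c("hypoglycemic", "insulin")),
    trigger_def("L6", "laboratory",
                "hyperglycemia above gestational targets",
                pred_any(
                  pred_lab("BG_fasting", ">", 5.3, "mmol/L",
                           requires_status = "gestational_or_pregestational",
                           requires_class = c("hypoglycemic", "insulin")),
                  pred_lab("BG_postprandial_1h", ">", 7.8, "mmol/L",
                           requires_status = "gestational_or_pregestational",
                           requires_class = c("hypoglycemic", "insulin")),
                  pred_lab("BG_postprandial_2h", ">", 6.7, "mmol/L",
                           requires_status = "gestational_or_pregestational",
                           requires_class = c("hypoglycemic", "insulin")),
                  pred_lab("BG_fasting", ">=", 6.1, "mmol/L",
                           requires_status = "none"),
                  pred_lab(c("BG_postprandial_1h", "BG_postprandial_2h"),
                           ">=", 7.8, "mmol/L", requires_status = "none")
                ),
                suspect_classes = "hyperglycemic"),
    trigger_def("L7", "laboratory",
                "acute kidney injury (SCr delta/ratio or oliguria)",
                pred_aki(), suspect_classes = "nephrotoxic"),
    trigger_def("L8", "laboratory",
                "coagulopathy (PT > 13 s / APTT > 35 s / INR >= 1.5) with bleeding",
                pred_all(
                  pred_any(pred_lab("PT", ">", 13, "s"),
                           pred_lab("APTT", ">", 35, "s"),
                           pred_lab("INR", ">=", 1.5, "ratio")),
                  pred_event("bleeding")
                ),
                suspect_classes = c("heparin", "anticoagulant")),
    trigger_def("L9", "laboratory",
                "platelets < 50 x 10^9/L (excluding physiologic/comorbid causes)",
                pred_lab("platelets", "<", 50, "10^9/L",
                         exclude_flags = c("physiologic_thrombocytopenia",
                                           "disease_related_cytopenia")),
                suspect_classes = "thrombocytopenic"),
    trigger_def("L10", "laboratory",
                "thyroid dysfunction under treatment (excluding thyroid disease)",
                pred_any(
                  pred_lab("TSH", ">", 4.0, "mIU/L",
                           exclude_flags = "thyroid_disease"),
                  pred_all(pred_lab("TPOAb", ">", 34, "IU/mL",
                                    exclude_flags = "thyroid_disease"),
                           pred_lab("TSH", "between", 2.5, "mIU/L",
                                    threshold_high = 4.0,
                                    exclude_flags = "thyroid_disease")),
                  pred_all(pred_lab("TSH", "<", 0.35, "mIU/L",
                                    exclude_flags = "thyroid_disease"),
                           pred_any(pred_lab("FT4", ">", 23, "pmol/L"),
                                    pred_lab("TT4", ">", 140, "nmol/L")))
                ),
                suspect_classes = "antithyroid"),
    trigger_def("L11", "laboratory",
                "WBC < 5.9 x 10^9/L or neutrophils < 3.9 x 10^9/L",
                pred_any(
                  pred_lab("WBC", "<", 5.9, "10^9/L",
                           exclude_flags = "disease_related_cytopenia"),
                  pred_lab("neutrophils", "<", 3900, "/uL",
                           exclude_flags = "disease_related_cytopenia")
                ),
                suspect_classes = "leukopenic"),
    trigger_def("L12", "laboratory",
                "liver injury by R ratio (hepatocellular/cholestatic/mixed)",
                pred_liver(), suspect_classes = "hepatotoxic"),
    # -- medication ------------------------------------------------------
    trigger_def("M1", "medication", "protamine given after heparin",
                pred_drug_after_drug("protamine", "heparin"),
                suspect_classes = "heparin"),
    trigger_def("M2", "medication",
                "glucocorticoid/antihistamine/calcium gluconate after allergic reaction",
                pred_drug_after_event(
                  c("glucocorticoid", "antihistamine", "calcium_gluconate"),
                  c("skin_allergic_reaction", "anaphylaxis")),
                suspect_classes = "any"),
    trigger_def("M3", "medication", "adrenaline for anaphylactic shock",
                pred_drug_after_event("adrenaline", "anaphylaxis"),
                suspect_classes = "any"),
    trigger_def("M4", "medication",
                "50% glucose after drug-induced severe hypoglycemia",
                pred_drug_after_event("glucose_50pct", "severe_hypoglycemia_event"),
                suspect_classes = c("hypoglycemic", "insulin")),
    trigger_def("M5", "medication", "naloxone/nalmefene after opioid poisoning",
                pred_drug_after_event("naloxone_nalmefene", "opioid_poisoning"),
                suspect_classes = "opioid_analgesic"),
    trigger_def("M6", "medication",
                "laxative or stool softener for drug-induced constipation",
                pred_drug_after_event("laxative", "drug_induced_constipation"),
                suspect_classes = c("opioid_analgesic", "other")),
    trigger_def("M7", "medication",
                "live bacteria preparation/antidiarrheal for drug-induced diarrhea",
                pred_drug_after_event("live_bacteria_antidiarrheal",
                                      "drug_induced_diarrhea"),
                suspect_classes = "any"),
    trigger_def("M8", "medication",
                "antiemetic after drug-induced vomiting (excluding morning sickness)",
                pred_drug_after_event("antiemetic", "drug_induced_vomiting",
                                      exclude_flags = "morning_sickness"),
                suspect_classes = "any"),
    trigger_def("M9", "medication",
                "IV calcium gluconate after magnesium sulfate",
                pred_drug_after_drug("calcium_gluconate", "magnesium_sulfate",
                                     route = "IV"),
                suspect_classes = "magnesium_sulfate"),
    # -- symptom ---------------------------------------------------------
    trigger_def("S1", "symptom", "skin allergic reaction",
                pred_event("skin_allergic_reaction"),
                suspect_classes = "any"),
    trigger_def("S2", "symptom", "hypotension / falls",
                pred_event("hypotension_fall"),
                suspect_classes = c("antihypertensive", "sedative_hypnotic",
                                    "magnesium_sulfate", "opioid_analgesic")),
    trigger_def("S3", "symptom",
                "blood pressure above 140/90 (excluding uncontrolled hypertension)",
                pred_event("bp_elevated",
                           attr_any = list(list(attr = "SBP", cmp = ">", value = 140),
                                           list(attr = "DBP", cmp = ">", value = 90)),
                           exclude_flags = c("preexisting_hypertension_uncontrolled",
                                             "disease_explained")),
                suspect_classes = uterotonics),
    trigger_def("S4", "symptom", "bleeding (nasal, gum, GI, purpura)",
                pred_event("bleeding"),
                suspect_classes = c("NSAID", "anticoagulant")),
    trigger_def("S5", "symptom", "weak contractions / postpartum hemorrhage",
                pred_event("weak_contraction_pph"),
                suspect_classes = c("sedative_hypnotic", "opioid_analgesic",
                                    "magnesium_sulfate")),
    trigger_def("S6", "symptom", "uterine hyperstimulation / rupture",
                pred_event("uterine_hyperstimulation"),
                suspect_classes = uterotonics),
    trigger_def("S7", "symptom", "edema not caused by underlying disease",
                pred_event("edema", exclude_flags = "disease_explained"),
                suspect_classes = c("glucocorticoid", "opioid_analgesic",
                                    "NSAID", "ergonovine")),
    trigger_def("S8", "symptom",
                "thromboembolic event (excluding spontaneous pregnancy embolism)",
                pred_event("thromboembolism",
                           exclude_flags = "spontaneous_pregnancy_embolism"),
                suspect_classes = "any"),
    trigger_def("S9", "symptom",
                "temperature rise >= 2 C or high fever/chills (excluding stress/infection)",
                pred_event("fever_chills",
                           attr_any = list(list(attr = "temp_rise", cmp = ">=", value = 2),
                                           list(attr = "temperature", cmp = ">", value = 39)),
                           exclude_flags = c("infection", "stress_related")),
                suspect_classes = "any"),
    trigger_def("S10", "symptom", "nervous system symptoms",
                pred_event("neuro_symptom"),
                suspect_classes = c("oxytocin", "prostaglandin", "antibiotic")),
    trigger_def("S11", "symptom",
                "gastrointestinal discomfort (excluding morning sickness)",
                pred_event("gi_discomfort", exclude_flags = "morning_sickness"),
                suspect_classes = "any"),
    trigger_def("S12", "symptom",
                "vaginal discomfort (excluding vaginitis and other disease)",
                pred_event("vaginal_discomfort",
                           exclude_flags = c("vaginitis", "disease_explained")),
                suspect_classes = "vaginal_topical"),
    trigger_def("S13", "symptom", "heart rate > 140/min or arrhythmia",
                pred_event("tachycardia_arrhythmia",
                           attr_any = list(list(attr = "heart_rate", cmp = ">", value = 140),
                                           list(attr = "arrhythmia", cmp = ">=", value = 1))),
                suspect_classes = uterotonics),
    trigger_def("S14", "symptom",
                "amniotic fluid abnormality (excluding PROM)",
                pred_event("amniotic_fluid_abnormal", exclude_flags = "PROM"),
                suspect_classes = uterotonics),
    # -- outcome ---------------------------------------------------------
    trigger_def("O1", "outcome", "ICU admission / rescue",
                pred_event("icu_admission_rescue"),
                suspect_classes = "any"),
    trigger_def("O2", "outcome",
                "abrupt cessation of long-term maintenance medication",
                pred_all(pred_event("abrupt_med_stop_event"),
                         pred_guard(requires_class = "long_term_maintenance")),
                suspect_classes = "long_term_maintenance"),
    trigger_def("O3", "outcome",
                "neonatal compromise (excluding cord torsion and other disease)",
                pred_event("neonatal_compromise", source = "neonate_events",
                           exclude_flags = c("cord_torsion", "disease_explained")),
                suspect_classes = c("opioid_analgesic", uterotonics)),
    trigger_def("O4", "outcome", "neonatal withdrawal symptoms",
                pred_event("neonatal_withdrawal", source = "neonate_events"),
                suspect_classes = c("opioid_analgesic", uterotonics))
  )
  trigger_registry("obstetric_39", "1.0", t)
}

#' The GTT medication-module comparator registry
#'
#' The 13 medication-module rules of the IHI Global Trigger Tool used as the
#' comparison method. Five of them (hypoglycemia below 2.8 mmol/L,
#' diphenhydramine administration, anti-emetic administration,
#' over-sedation/hypotension, abrupt medication stop) are exercised by the
#' study fixture; the remaining eight complete the white-paper module
#' roster.
#'
#' @return A `trigger_registry` with 13 triggers.
#' @export
gtt_registry <- function() {
  wp <- "white paper"
  t <- list(
    trigger_def("GTT-M1", "laboratory", "PTT > 100 s",
                pred_lab("APTT", ">", 100, "s"),
                suspect_classes = c("heparin", "anticoagulant"),
                provenance = wp),
    trigger_def("GTT-M2", "laboratory", "INR > 6",
                pred_lab("INR", ">", 6, "ratio"),
                suspect_classes = "anticoagulant", provenance = wp),
    trigger_def("GTT-M3", "laboratory", "WBC < 3 x 10^9/L",
                pred_lab("WBC", "<", 3, "10^9/L"),
                suspect_classes = "leukopenic", provenance = wp),
    trigger_def("GTT-M4", "laboratory", "glucose < 2.8 mmol/L",
                pred_lab(bg_analytes, "<", 2.8, "mmol/L"),
                suspect_classes = c("hypoglycemic", "insulin")),
    trigger_def("GTT-M5", "laboratory", "rising serum creatinine",
                pred_aki(), suspect_classes = "nephrotoxic", provenance = wp),
    trigger_def("GTT-M6", "medication", "vitamin K administration",
                pred_drug("vitamin_k"), suspect_classes = "anticoagulant",
                provenance = wp),
    trigger_def("GTT-M7", "medication", "diphenhydramine administration",
                pred_drug("diphenhydramine"), suspect_classes = "any"),
    trigger_def("GTT-M8", "medication", "flumazenil administration",
                pred_drug("flumazenil"), suspect_classes = "sedative_hypnotic",
                provenance = wp),
    trigger_def("GTT-M9", "medication", "naloxone administration",
                pred_drug("naloxone_nalmefene"),
                suspect_classes = "opioid_analgesic", provenance = wp),
    trigger_def("GTT-M10", "medication", "anti-emetic administration",
                pred_drug("antiemetic"), suspect_classes = "any"),
    trigger_def("GTT-M11", "symptom", "over-sedation / hypotension",
                pred_event("hypotension_fall"),
                suspect_classes = c("sedative_hypnotic", "antihypertensive",
                                    "opioid_analgesic", "magnesium_sulfate")),
    trigger_def("GTT-M12", "medication", "abrupt medication stop",
                pred_drug(drug_class_vocabulary(), abrupt_stop = TRUE),
                suspect_classes = "any"),
    trigger_def("GTT-M13", "symptom", "rash",
                pred_event("rash"), suspect_classes = "any", provenance = wp)
  )
  trigger_registry("gtt_medication", "1.0", t)
}
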