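# Small record builders shared across tests.

# rendering helpers (mirror the package's report rounding: half-up, 2 dp)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
pct <- function(x) round_half_up(100 * x, 2)

make_record <- function(record_id = "T1", age = 28, ga = 38, stay_days = 4,
                        delivery = "vaginal", diabetic = "none",
                        comorbidity = character(), labs = list(),
                        exposures = list(default_exposure()),
                        events = list(), neonate_events = list(),
                        srs = character()) {
  patient_record(
    record_id = record_id, age = age, gestational_age = ga,
    admission_time = 0, discharge_time = stay_days * 24,
    delivery_mode = delivery, diabetic_status = diabetic,
    comorbidity_flags = comorbidity, labs = labs, exposures = exposures,
    events = events, neonate_events = neonate_events,
    srs_reported_event_ids = srs
  )
}

default_exposure <- function(id = "DX", classes = "antibiotic",
                             start = 10, stop = 20, route = "other",
                             abrupt = FALSE) {
  medication_exposure(id, "test drug", classes, start, stop, abrupt, route)
}

# cached fixture pipeline shared by the heavier tests
fixture_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- build_study_fixture()
      reg <- obstetric_registry()
      gtt <- gtt_registry()
      hits <- screen_cohort(reg, fx$cohort)
      gtt_hits <- screen_cohort(gtt, fx$cohort)
      ades <- consolidate_ades(fx$cohort, fx$assessments, hits, gtt_hits)
      cache <<- list(fx = fx, reg = reg, gtt = gtt, hits = hits,
                     gtt_hits = gtt_hits, ades = ades)
    }
    cache
  }
})
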