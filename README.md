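# obstrigger

Rule-based detection of adverse drug events (ADEs) in obstetric inpatient
records.

Pregnant inpatients are a blind spot of routine pharmacovigilance: altered
pharmacokinetics, complications that mimic drug effects, and spontaneous
reporting systems (SRS) that capture only a sliver of what happens.
*Trigger tools* close the gap by screening every chart for predefined
clues — an abnormal lab, an antidote given, a symptom, an outcome — and
sending only flagged charts to focused human review. `obstrigger`
implements an obstetric-specific trigger tool as an automated pipeline for
people who study or run such surveillance: a declarative rule engine with a
39-trigger obstetric registry (12 laboratory, 9 medication, 14 symptom,
4 outcome rules), the IHI Global Trigger Tool (GTT) medication module as a
comparator, WHO-UMC causality and CTCAE v5 severity adjudication, the full
performance-metric surface, and a registry refinement procedure.

The quantities at the core are simple and unforgiving. For trigger *t*
with `pos(t)` positive hits of which `ade(t)` are linked to an adjudicated
ADE,

```
PPV(t)        = ade(t) / pos(t)
overall PPV   = Σ ade(t) / Σ pos(t)
ADE incidence = 100 · n_ADE / n_records        (per 100 admissions)
              = 1000 · n_ADE / patient-days    (per 1000 patient-days)
detection rate(method) = ADEs detected by method / all adjudicated ADEs
```

where an ADE is a clinical event whose WHO-UMC causality is *certain* or
*probable* (a deterministic first-match cascade over structured reviewer
evidence), its severity a CTCAE grade 1–5 from a precedence cascade, and
hit→ADE linkage runs through shared evidence ids — many hits, one event.

## Worked example

The package ships a deterministic 300-record study fixture (no external
data are required):

```r
library(obstrigger)

fx   <- build_study_fixture()            # cohort + reviewer assessments
reg  <- load_registry("obstetric_39")
hits <- screen_cohort(reg, fx$cohort)    # screening mode: the clue fires,
                                         # suspect drugs are attached
ades <- consolidate_ades(fx$cohort, fx$assessments, hits,
                         screen_cohort(load_registry("gtt_medication"),
                                       fx$cohort))
cohort_summary(fx$cohort, hits, ades, reg)
```

```
n_records                   300
n_positive_records          120
total_hits                  154
total_ade_flagged_hits       56
n_ades                       49
total_patient_days         1301
positive_record_rate          0.4000000
hits_per_positive_record      1.2833333
overall_ppv                   0.3636364
ades_per_100_admissions      16.3333333
ades_per_1000_patient_days   37.6633359
n_triggers_positive          22
n_triggers_total             39
```

Reading: 154 trigger hits flagged 120 of 300 admissions (positive rate
40.00%, 1.28 hits per flagged chart); 56 of the 154 hits pointed at an
adjudicated ADE (overall PPV 36.36%); adjudication found 49 ADEs — an
incidence of 16.33 per 100 admissions and 37.66 per 1000 patient-days.
Per-trigger precision comes from `trigger_performance()`; for example a
single low-potassium hit with no causally linked drug renders as

```
 trigger_id     module positive_triggers ades   ppv
         L1 laboratory                 1    0 0.00%
```

and a single record is screened with `evaluate_trigger()`:

```r
evaluate_trigger(reg$triggers[[1]], fx$cohort[[104]])
#> # A tibble: 1 × 5
#>   record_id trigger_id  time evidence_ids suspect_exposure_ids
#> 1 R104      L1            30 <chr [1]>    <chr [1]>
```

`refine_registry()` applies the post-review revision (drop the four silent
triggers, tighten the calcium-gluconate and laxative rules), yielding the
35-trigger revised registry; `generate_cohort()` simulates cohorts with
known truth for calibration studies; `run_pipeline()` executes
read → include → screen → adjudicate → report against JSONL/CSV inputs and
writes CSV/JSON reports. A thin command-line wrapper lives at
`inst/cli/obstrigger.R` (`screen`, `run`, `refine`, `simulate`, `fixture`,
`registry`).

The methods vignette (`vignettes/obstetric-trigger-tool.Rmd`) documents the
rule semantics, the adjudication cascades, the fixture's construction and
the generator's scope.

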