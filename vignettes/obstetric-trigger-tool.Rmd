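---
title: "An obstetric adverse drug event trigger tool: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An obstetric adverse drug event trigger tool: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obstrigger)
```

## The problem

Adverse drug events (ADEs) in obstetric inpatients are systematically
under-captured by spontaneous reporting: pregnancy alters pharmacokinetics,
complications mimic drug effects, and mild events go unrecorded. Trigger
tools address this by screening every chart for predefined *clues* — an
abnormal laboratory value, an antidote administration, a symptom, an
outcome — and focusing human review on the flagged charts. The IHI Global
Trigger Tool (GTT) standardised this method; its medication module, however,
was designed for general adult inpatients. `obstrigger` implements an
obstetric-specific trigger set of 39 rules in four modules (12 laboratory,
9 medication, 14 symptom, 4 outcome), the 13-rule GTT medication module as
a comparator, and everything needed to run, evaluate and refine such a tool
on structured inpatient records.

## Data model

A cohort is a list of single-admission records serialized as JSON Lines
(one record per line). Timestamps are **hours since admission**: every
trigger window in the rule set (48 hours, 7 days) is relative, so an
absolute calendar is unnecessary; length of stay in days is
`(discharge - admission) / 24`. Records carry labs (controlled analyte
codes with unit whitelists), medication exposures (free-text drug name plus
controlled *class tags* such as `magnesium_sulfate` or `hypokalemic`, a
half-open administration interval, route, and an abrupt-stop flag),
clinical events (controlled codes with a `key = value` attribute map and
exclusion flags), neonate events, and the ids of events reported to the
spontaneous reporting system (SRS).

Two modelling choices deserve emphasis:

* **Canonical units.** All comparisons happen after conversion to one
  canonical unit per analyte (mmol/L for electrolytes and glucose, mg/dL
  for creatinine — the unit its delta rule is written in — 10^9/L for cell
  counts, seconds for clotting times, U/L for enzymes). Conversions use
  fixed clinical-chemistry factors (creatinine 88.4 µmol/L per mg/dL;
  glucose 18.016 mg/dL per mmol/L) and round-trip to 1e-9 relative
  tolerance.
* **Exclusions are data, not inference.** Prose exclusions in the rule set
  ("excluding physiologic changes", "excluding morning sickness") encode
  chart-reviewer judgement that cannot be recomputed from labs. They are
  explicit flags supplied by the data producer — record-level comorbidity
  flags and event-level exclusion flags — and predicates simply refuse to
  fire on flagged findings.

The inclusion filter retains records with gestational age ≥ 28 weeks,
maternal age 16–65 years, stay strictly longer than 48 h, and at least one
medication exposure. It is a filter, not validation: rejected records are
returned with named reasons.

## The rule engine

Triggers are declarative predicate trees (`pred_lab()`, `pred_event()`,
`pred_drug()`, `pred_drug_after_event()`, `pred_drug_after_drug()`,
`pred_aki()`, `pred_liver()`, and the combinators `pred_all()`,
`pred_any()`, `pred_not()`, `pred_guard()`). Leaves yield *matches* —
qualifying findings with a time and evidence ids — and guards yield
record-level booleans. Registries serialize to YAML, so the shipped rule
sets are data, inspectable and replaceable.

Evaluation semantics, fixed across the package:

* **Screening vs strict.** The published table separates the clue
  ("Triggers" column) from the drug context ("Interpretation" column). In
  the default screening mode the clue alone fires, and exposures matching
  the drug context are attached to the hit as *suspects* for adjudication;
  in strict mode hits without a co-occurring suspect are dropped. Screening
  is the default because the observed data demand it: the hypoglycemia
  trigger has 17 positives with zero confirmed ADEs, so positives clearly
  do not require confirmed drug causation. Strict-mode hits are provably a
  subset of screening-mode hits.
* **Strict inequalities as printed.** `K < 3.3` does not fire at exactly
  3.3; `SBP > 140` does not fire at 140. The source uses strict comparators
  throughout and never states that boundary equality should fire; the one
  place this is ambiguous (potassium, with `<` on one side and `>` on the
  other) is flagged in the registry for sensitivity analysis.
* **One hit per finding, capped per day.** A hit is one qualifying finding;
  repeated measurements of the same abnormality within a calendar day are
  chart-review duplicates, not new clues, so per-trigger-per-record hits
  are capped at one per day. Published frequencies are chart-review counts,
  not laboratory-row counts.
* **Windows.** Sequence predicates ("antidote after event", "drug after
  drug") use a 48-hour window by default — the horizon the rule set itself
  uses for its creatinine delta rule — and suspects co-occur with a finding
  at time *t* iff `start ≤ t < stop + lookback` with a registry-level
  48-hour lookback. Both are configurable per registry.
* **Determinism.** The hit table is sorted by (record, trigger, time);
  permuting records or a record's internal lists cannot change the output,
  and a record whose evaluation fails (an event missing an attribute a
  predicate needs) is excluded with a per-record error in the run report
  rather than poisoning the run.

Two laboratory rules are algorithmic rather than threshold comparisons.
The **liver-injury rule** computes the R ratio
`(ALT/ALT_ULN) / (ALP/ALP_ULN)` and classifies hepatocellular
(ALT ≥ 3·ULN, R ≥ 5), cholestatic (ALP ≥ 2·ULN, R ≤ 2) or mixed
(both, 2 < R < 5) patterns, firing on any of them. Reference upper limits
are record-configurable with defaults ALT 40 U/L and ALP 150 U/L, since the
source uses ULN symbolically without printing its laboratory's ranges. The
**acute kidney injury rule** fires when creatinine rises ≥ 0.3 mg/dL
within 48 h (against the minimum of the preceding 48-hour window), reaches
1.5× baseline within seven days (baseline = earliest flagged value, else
the earliest value), or urine output stays below 0.5 mL/kg/h for more than
6 h continuously.

The thyroid rule's hyperthyroid branch ("TSH decreases, TT4 and FT4
increase") has no printed thresholds; it is formalized here as TSH below
0.35 mIU/L with FT4 above 23 pmol/L or TT4 above 140 nmol/L — ordinary
reference-interval bounds — while the hypothyroid branch is implemented
exactly as printed (TSH > 4.0 mIU/L, or TPOAb-positive with TSH 2.5–4.0).

### The comparator registry

The GTT medication module ships as a separate 13-rule registry. Five rules
(glucose < 2.8 mmol/L, diphenhydramine administration, anti-emetic
administration, over-sedation/hypotension, abrupt medication stop) are the
ones the study exercised; the other eight complete the module roster and
are marked `provenance = "white paper"`. Two deliberate modelling splits
keep the comparator and the obstetric set from colliding:

* The obstetric "abrupt cessation" outcome rule reads a documented
  cessation *event* on records carrying long-term maintenance therapy; the
  GTT abrupt-stop rule reads the exposure-level `abrupt_stop` flag. The two
  observed different counts in the study, so they are distinct predicates
  over distinct data channels.
* The GTT "rash" rule reads a dedicated `rash` event code, distinct from
  the obstetric `skin_allergic_reaction` code, mirroring the fact that the
  study's comparator results show no rash row.

## Adjudication

Causality follows the WHO-UMC categories, formalized as a deterministic
first-match cascade so that each published criterion maps to exactly one
branch: information insufficient/contradictory → unassessable; more data
needed → conditional; timing unknown → unassessable; timing improbable →
unlikely; plausible timing + alternatives excluded + positive dechallenge +
(pharmacologically definitive or positive rechallenge) → certain;
plausible/reasonable timing + alternatives excluded + positive dechallenge
→ probable; otherwise possible. The three-level alternative-explanation
scale folds "unlikely to be attributed to disease" into `excluded`; this
makes "probable" require an excluded alternative, trading reviewer latitude
for reproducibility (the panel-consensus step of the manual workflow is
out of scope). Only `certain` and `probable` events become ADEs. The
cascade is total, deterministic, and monotone in dechallenge — properties
the test suite verifies by exhaustive enumeration of the 864-point evidence
grid.

Severity is CTCAE v5 as a precedence cascade over reviewer findings: death
→ 5; life-threatening → 4; hospitalization caused/prolonged or disabling →
3; moderate/local intervention or instrumental-ADL limitation → 2; else 1.
Setting any flag never lowers the grade.

**Consolidation** maps many hits to one event: each assessed event with
causality certain/probable yields exactly one ADE regardless of how many
triggers hit it. A hit *detects* an ADE when its evidence ids intersect the
event's finding trail (the clinical events, laboratory abnormalities and
treatment exposures the reviewer tied to the event) or its implicated
exposures. Detection is evidence-based, not suspect-based, by design:
linking through attached suspect exposures would attribute every ADE in a
record to every co-fired "any-drug" trigger, which collapses per-trigger
precision into record-level precision. Antidote-style rules (anti-emetic
given, antihistamine given) are linked through the finding trail, which
includes the treatment exposure the reviewer tied to the event. Organ class
comes from a static finding-code → organ map shipped with the package,
since the source reports organ distributions without defining a mapping.

## Metrics

All rates are exact integer ratios; percentages are rounded half-up to two
decimals only at rendering. Per-trigger PPV is ADE-linked hits over
positive hits (undefined, rendered "-", for silent triggers); overall PPV
is ADE-linked hits over all hits and equals the hit-weighted mean of the
defined per-trigger PPVs. Cohort incidence is reported per 100 admissions
and per 1000 patient-days; the three detection methods (obstetric
registry, GTT comparator, SRS) are compared over the same adjudicated-ADE
denominator.

Proportion intervals default to Wald, with Wilson available (and
cross-checked in tests against the score interval of
`prop.test(correct = FALSE)`). The source's printed intervals are
internally impossible — one upper bound exceeds 100% — so no interval
bounds are reproduced anywhere; point estimates carry all comparisons.

The risk-factor model is an ordinary maximum-likelihood logistic regression
(`stats::glm`) of "record has ≥ 1 ADE" on age, stay, drug counts,
antibacterial count, injection count and delivery-mode indicators, with
Wald intervals on the log-odds scale (matching the symmetric-in-log ranges
such models report). Constant covariates and (quasi-)complete separation
fail with explicit diagnostics rather than silent divergence. The published
coefficient table is not reproducible without the raw charts; the model is
validated instead by parameter recovery on simulated cohorts with known
log-odds (a planted antibacterial log-OR of −1.3 is recovered within
±0.25 at n = 2000, and a null covariate's 95% CI covers 1 at close to
nominal rate over seeded replicates).

## Refinement

The post-review revision procedure takes a registry plus its performance
table and applies declarative revision rules: `drop_zero_hit` (refusing to
drop a trigger that fired) and `predicate_amendment`. The shipped study
rule set drops the four silent triggers (protamine, bleeding,
thromboembolism, amniotic-fluid) and tightens two low-precision ones:
IV calcium gluconate only counts with co-occurring magnesium above
5 mmol/L (the bare clue is routine prophylaxis in pre-eclampsia — 15
positives, zero ADEs), and the laxative rule is restricted to non-cesarean
patients (post-surgical laxative use is routine care — 36 positives, two
ADEs, both non-cesarean). The magnesium threshold is kept as printed
(5 mmol/L) even though it exceeds the hypermagnesemia laboratory
trigger's 3.5 mmol/L, and is configurable. The amended laxative rule keeps
the original 48-hour window — the revision as printed changes only the
population restriction. The result is the 35-trigger revised registry
(12/8/11/4); both amendments strictly add conjuncts, so the revised
registry can never produce more hits than the original on any cohort — a
property the tests check on fixed and simulated cohorts.

## The study fixture

The study's 300 charts are not deposited, so validation rests on a
**deterministic fixture**: a 300-record cohort constructed so that the full
pipeline reproduces the published count structure exactly — 154 hits on
120 records (22 of 39 triggers positive), 56 ADE-linked hits collapsing to
48 trigger-detected events, 49 ADEs total with one reached by no trigger,
the GTT comparator's 31 hits / 10 ADE-linked hits / 9 detected ADEs, 7
SRS-reported ADEs, severity 17/27/5 over grades 1–3, organ classes
17 cardiovascular / 12 gastrointestinal / 8 reproductive / 7 fetal with 5
events across the remaining classes, and 1301 patient-days.

The published aggregates under-determine the fixture; the remaining
freedom is fixed by documented choices:

* **Patient-days = 1301.** The total is never printed. It is the unique
  integer consistent with both printed per-1000-patient-day rates (36.89
  for the 48 trigger-detected events and 37.66 for all 49); stays are
  integers in 3–10 days (strictly above the 48-hour inclusion bound)
  summing to 1301, mean 4.3367 — rendering as the published 4.34.
* **Hit-to-record allocation.** 48 ADE records carry the 56 ADE-linked
  hits; eight of them carry two co-adjudicated hits each (four records
  with elevated blood pressure plus tachycardia after oxytocin; postpartum
  hemorrhage escalating to ICU; hypotension escalating to ICU; vomiting
  with an anti-emetic given; an allergic reaction treated with
  diphenhydramine). 72 further records carry the 98 non-ADE hits with 26
  stacked pairs (15 records pairing post-cesarean laxative use with
  calcium gluconate after magnesium sulfate; 8 pairing laxative use with
  hypoglycemia; 2 pairing uterine hyperstimulation with fetal distress;
  one pairing an allergy with hypotension). These pairings are clinically
  coherent and produce the organ-class totals without further tuning.
* **The GTT overlap.** The comparator's printed numbers force 10 ADE-linked
  hits onto 9 distinct events, so one over-sedation record also carries the
  abrupt-stop clue (the implicated sedative was stopped abruptly); the
  comparator's hypoglycemia rule shares its 17 records with the obstetric
  hypoglycemia trigger, and its over-sedation rule shares all 10
  hypotension records.
* **The undetected ADE** is an untreated drug-induced diarrhea — an event
  with no matching clue (the antidiarrheal rule requires the treatment) —
  reported to nobody, consistent with the observed row structure.
* Demographics are constructed exactly: mean age 27.45 (range 18–43),
  delivery mix 115 cesarean / 162 vaginal / 23 fetal-preservation.

Three extra records exercise exclusion guards (morning-sickness nausea,
physiologic thrombocytopenia, uncontrolled chronic hypertension) and fire
nothing.

## The stochastic generator

`generate_cohort()` plants each trigger's minimal finding set independently
per record with a firing probability, marks plants as true ADEs with a
conditional probability, and emits the matching reviewer assessments plus a
truth table. Defaults are the study conditions: 300 records, the observed
demographic distributions, and per-trigger rates equal to the observed
ones. The planting recipes are mutually non-interfering with one known,
documented exception: the coagulopathy recipe's bleeding event also
satisfies the bleeding symptom trigger (the rule set genuinely reads the
same finding twice), so that pair is excluded from recovery comparisons.
Validation uses planted-rate recovery within binomial 3-SE bounds at
n = 5000 (at least 36 of 39 triggers), per-trigger PPV recovery against
the truth annotations, and the logistic parameter recovery described
above. A risk-model mode replaces per-trigger planting with a
covariate-driven record-level outcome for regression validation.

What the generator does *not* emulate: pharmacokinetics, dose-response,
correlated comorbidity structure, free-text documentation, or reviewer
disagreement. Passing recovery tests therefore demonstrates that the
pipeline measures what was planted — not that the trigger set would attain
the same operating characteristics on real charts.

## Numerical and engineering choices

* Rounding is half-up to two decimals, applied only at rendering
  (`36.36%`, `97.96%`); all internal arithmetic is exact ratio.
* Problem sizes in the shipped validation: the 300-record fixture for all
  exact checks; n = 5000 for rate recovery; n = 2000 for regression
  recovery; 60 seeded replicates at n = 400 for CI coverage. These keep
  the whole suite in a few minutes on one core while leaving Monte-Carlo
  error well inside the asserted bounds.
* Ties and ordering: hit tables sort lexicographically; registry order
  never affects results; the evaluator is pure (no cross-record state), so
  aggregation commutes with screening.
* The pipeline writes a manifest with input digests; double runs are
  byte-identical apart from recorded timings.

## Limitations

The tool screens structured data only: medication errors that never reach
labs, events or exposure records are invisible to it, which is exactly the
failure mode of the one undetected fixture ADE. The causality cascade is a
reproducible formalization of criteria that in practice admit reviewer
judgement; site-specific reference ranges (ULN, thyroid cut-offs) should be
configured rather than defaulted. The published confidence intervals and
regression coefficients are irreproducible from printed information and are
deliberately out of scope.
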