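---
title: "Measuring statin adherence from claims and relating it to mortality: summary versus repeated measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring statin adherence from claims and relating it to mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcsurv)
```

## The scientific problem

Observational claims studies estimate the mortality benefit of taking
statins as prescribed by classifying each patient's *proportion of days
covered* (PDC) — the fraction of follow-up days on which dispensed supply
was available — and relating that classification to survival. Two
measurement strategies are in common use and can disagree sharply:

* **Method A (fixed summary).** One PDC over the whole follow-up, entered
  into a Cox model as a baseline covariate.
* **Method B (repeated measures).** PDC re-measured in consecutive
  102-day intervals and entered as a time-dependent covariate in
  counting-process form.

The repeated-measures approach is more sensitive to changes in behaviour,
but it is also more exposed to *survival bias*: failing health late in
follow-up depresses both refill behaviour and survival, so recent
adherence can look protective even when it causes nothing. `pdcsurv`
implements both measurement pipelines over a shared coverage engine, and
a synthetic claims generator whose scenarios make the divergence (and its
absence) reproducible.

## The adjusted coverage engine

Raw PDC overestimates exposure when refills arrive early or when supply
extends past the end of observation. The engine applies three
adjustments, all on integer days with half-open intervals `[start, end)`:

1. **Completion-date chaining.** Each dispensation is assigned a
   completion date; a refill obtained before the previous completion date
   is deferred, `start_i = max(day_i, end_(i-1))`, so overlapping supply
   is stockpiled, never double-counted. Carryover is uncapped: unused
   supply from one measurement interval flows into the next.
2. **End-of-follow-up truncation.** Supply beyond the last follow-up day
   is discarded from the calculation.
3. **Hospital-day removal.** Days spent in hospital are removed from the
   calculation, because inpatient dispensing is invisible to outpatient
   claims. The default (`hospital_mode = "compress"`) performs the whole
   computation on a compressed timeline from which hospital days are
   deleted, which simultaneously removes them from the denominator and
   pauses consumption of outpatient supply while the patient is an
   inpatient — we chose pausing because the inpatient's medication comes
   from the hospital, so home supply plausibly sits unused. The
   alternative reading, that hospital days merely leave the denominator
   while supply keeps draining, is preserved under
   `hospital_mode = "denominator_only"`. A hospital stay covers the
   admission day through the day before discharge; the discharge day
   counts as a day at home, so a fill dispensed at discharge starts that
   day.

Both measurement methods read off one `CoverageSchedule` per person, so
their covered-day inputs are identical by construction:
`summary covered days = Σ interval covered days` exactly, and the summary
PDC is the length-weighted mean of the interval PDCs. The test suite
verifies the engine against a literal day-by-day supply-stack simulation
on 1,000 random refill/hospitalization histories.

Classification uses the conventional cuts: *optimal* adherence is
PDC ≥ 0.80 (inclusive); the three-level sensitivity scheme is
low ≤ 0.20 < middle < 0.80 ≤ optimal. We read the low boundary as
inclusive (≤ 20%); the two readings differ only at exactly 0.20.

## Cohort selection

`select_cohort()` implements a new-user ACS cohort: age ≥ 30 at the index
discharge, 1825 days of prior continuous coverage, no statin dispensed in
the 365 days before the index admission (washout, measured from the
admission day since "prior to the hospitalization" most naturally
predates admission), a first statin fill within 90 days of discharge
(inclusive: a fill on the discharge day qualifies, so the fill-to-index
difference lies in `[0, 90]`), survival with coverage for at least 102
days after that fill, and exclusion of persons whose only qualifying
hospitalizations were revascularizations without an ACS diagnosis.
Criteria are applied in a fixed order — age, prior coverage,
revascularization-only, washout, fill window, minimum survival — which
affects only the exclusion-flow tally, never membership (membership is an
intersection). Age is completed years by integer-day arithmetic
(`floor(days / 365.25)`). Diagnosis and drug code sets are configuration;
the synthetic data uses symbolic codes (`MI`, `UA`, `REVASC_ONLY`,
`statin_A`, `statin_B`).

## The two survival models

Time at risk begins at the close of the first measurement interval — the
observed day corresponding to 102 adherence days after the first fill
(exactly day 102 when no hospitalization intervenes). Anchoring the
origin to the interval grid keeps the counting-process rows aligned with
the measurement intervals and makes per-person at-risk time identical in
the two datasets, a property the tests assert exactly. A person censored
precisely at the origin contributes no at-risk time and is dropped with a
logged count.

Method A enters the summary classification as a fixed covariate on
`(0, followup_end]`. Method B contributes one row per interval from the
second interval onward; by default the covariate over `(start, stop]` is
that same interval's PDC class (`timing = "concurrent"`), which matches
the design in which adherence in the final interval is associated with
death in that interval; `timing = "lagged"` is available when a
strictly predictive covariate is wanted. The incomplete final interval is
retained with its true length as denominator; analyses labelled "last
completed interval" use the last interval spanning the full 102 days.
Models are fitted by partial likelihood via `survival::coxph()` with the
Efron tie correction (lower bias than Breslow; the choice is otherwise
unconstrained). Crude fits contain the adherence term alone; adjusted
fits add a configurable baseline covariate vector (the generator emits
age group, sex, revascularization and a comorbidity flag).

Diagnostics follow standard practice: Schoenfeld residuals per covariate
keyed by event time with the zero-slope score test against untransformed
event time as the programmatic criterion, log(−log S(t)) curves emitted
as plot data for the visual check (never auto-judged), and collinearity
screening by variance inflation factors computed from the definition
`VIF_j = 1/(1 − R²_j)`, flagging values above 10, with exact collinearity
reported as infinite.

Kaplan-Meier description uses the ordinary product-limit estimator for
the summary grouping and, for the time-dependent grouping, the extended
(Simon–Makuch-style) estimator in which a subject's person-time is
attributed to the group matching their current interval class — the
natural construction when group membership changes over follow-up.

## What the synthetic generator emulates

`generate_bundle()` emits the three administrative tables (registry with
baseline covariates, hospitalizations including the index ACS episode,
dispensations) for a cohort that passes `select_cohort()` by
construction, plus a per-interval truth table for testing. Default study
conditions: a 15-year study window (integer days 1826–7304 from the
epoch, i.e. a 1994–2008-style window after five years of lead-in
coverage), index discharges uniform over the window, ages
normal(64.8, 12.3) truncated to ≥ 31, 69.2% male, 58.5% with
revascularization, 36.7% with the comorbidity flag, first fill at
discharge with probability 0.6 and otherwise a short geometric delay
capped at 90 days, 34-day fill quantities, and a baseline hazard of
1e-4 deaths per person-day beyond the first interval.

Refills follow a renewal process: when supply runs out, the gap to the
next fill is geometric with per-day probability
`plogis(fill_alpha + b + gamma * H + trend * years)`; with probability
0.2 the refill instead arrives 1–7 days early, exercising the deferral
rule without changing coverage. Two latent quantities drive behaviour:

* `b`, a stable person-level propensity (logit-normal, SD 2.2). With
  `fill_alpha = -2.2` this reproduces the wide, persistent between-person
  adherence spread seen in claims cohorts — population summary PDC mean
  ≈ 0.70, SD ≈ 0.29, roughly half the cohort optimal. This heterogeneity
  is not decoration: with a homogeneous refill propensity, an "optimal"
  summary classification can essentially only arise from a short, noisy
  measurement window, which deaths disproportionately have, and the
  summary method then shows a large spurious hazard even under the null.
  Stable heterogeneity is what anchors classifications to behaviour
  rather than to window length.
* `H`, an interval-resolution latent health random walk (innovation SD
  0.4). Health is interval-resolution deliberately, matching the 102-day
  measurement grid.

Mortality is piecewise-constant per interval,
`lambda = baseline_hazard * exp(beta * A + theta * H)` with `A` the
current interval's optimal-adherence indicator, sampled by inversion of
the cumulative hazard. The hazard is zero during the first interval, so
every generated person survives the 102-day eligibility window — this
also mirrors the design argument that deaths in the first three months
of therapy are not attributable to adherence. When a death falls inside
an interval, the death day is placed within that interval at a day where
the classification of the death-truncated interval equals the
full-interval classification that generated the hazard (the interval end
always qualifies, so a valid day exists). The generator's truth is
defined at interval resolution; this rule pins down the day-resolution
realization consistently, so the covariate the engine measures is the
covariate that drove the hazard for deaths and censored subjects alike.

Scenarios:

* **null** — `beta = 0`, `gamma = 0`: no effect, no confounding.
* **causal** — `beta = log(0.75)`: a genuine 25% hazard reduction while
  currently adherent, the canonical protective effect size for this
  literature.
* **survival_bias** — `beta = 0`, `gamma = 1`, plus a deterministic drop
  of 1 latent-health unit in the death interval (half a unit in the
  preceding interval), applied after the death time is sampled (valid
  because the hazard ignores adherence when `beta = 0`). Dying people
  stop refilling shortly before death; recent adherence becomes a marker
  of survival, not a cause. The decline magnitude is calibrated so the
  scenario exhibits its defining contrast at `n = 9000`: the
  repeated-measures HR sits well below 1 with its confidence interval
  excluding 1, while the summary-measure HR stays compatible with 1 —
  the qualitative signature of survival bias. The latent-health effect
  on the hazard (`theta`) defaults to 0 in all presets: a persistent
  hazard-health link would confound the summary measure too and erase
  the scenario's defining asymmetry; it remains available as a knob.
* **improving_trend** — adds a calendar improvement in fill propensity
  (`trend_slope = 0.12` per year on the logit), emulating secular
  adherence gains over a 15-year window.

Mid-follow-up hospital episodes are off by default and available via
`hosp_rate`; they exist to exercise timeline compression, not to model
care, and the presets used for the inference properties keep them off so
the generator's interval grid and the engine's coincide exactly.
Determinism: each person consumes a dedicated RNG substream keyed by
person index, so bundles are byte-identical across runs for a given
config and invariant to `n_persons` prefix changes in structure.

## What passing tests do and do not show

The generator emulates the *structure* of an administrative cohort —
entry flow, refill renewals, interval measurement, censoring — not any
particular population. Real claims add features the generator omits:
dose changes and switching with different days-supplied, non-geometric
refill habits (payday cycles, vacation stockpiling), informative
coverage termination, coding error in diagnoses and dates, and
confounding by indication. Passing the property suite shows the
*machinery* is correct (the coverage arithmetic is exact, the estimators
recover known effects, the two methods agree when they must, the
survival-bias signature appears when built in); it does not certify any
substantive estimate on real data.

## Numerical choices and problem sizes

Integer-day arithmetic throughout; no partial days. Zero-denominator
adherence (a fully hospitalized window) is a distinct missing state, and
such persons are excluded from model datasets with a logged count. The
method-equivalence check requires coefficient agreement within 1e-6;
equality is exact in structure (identical risk sets and covariate
values), so the tolerance only absorbs solver arithmetic. Replicate
studies in the test suite run at the sizes stated in their tests —
1,000 random histories for the coverage oracle, 50 replicates of
n = 5,000 for causal recovery, 200 replicates of n = 1,000 for type-I
error, a single n = 9,000 run for the survival-bias contrast — sizes
chosen to hold Monte-Carlo error well below the assertion margins while
keeping the default suite comfortably runnable on one CPU.

## Known limitations

* The washout uses the index admission day; cohorts defined from the
  discharge day would differ for persons filling statins during the
  index stay (impossible in the generator, possible in real data).
* The concurrent covariate timing in Method B is a modelling choice, not
  a discovery; `timing = "lagged"` gives the strictly predictive
  variant, and analyses should report which was used.
* The generator's hospital episodes are independent of health — they
  exist to exercise timeline compression, not to model care-seeking.
* PDC treats possession as exposure; actual ingestion is unobservable in
  claims, here and everywhere.
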