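# pdcsurv

Medication-adherence measurement from pharmacy claims, and its
consequences for survival analysis.

`pdcsurv` is for pharmacoepidemiologists and biostatisticians who
estimate the association between refill adherence and mortality from
administrative data. It implements an **adjusted proportion-of-days-covered
(PDC) engine** — completion-date supply chaining with early-refill
deferral, truncation of supply beyond the end of follow-up, and removal
of hospitalized days — and then compares the two standard ways of putting
adherence into a Cox proportional-hazards model of death:

* **Method A, fixed summary**: one PDC over the whole follow-up,
  dichotomized at the conventional optimum (PDC ≥ 0.80) and entered as a
  baseline covariate;
* **Method B, repeated measures**: PDC re-measured over consecutive
  102-day intervals (three 34-day fills) with carryover of unused supply,
  entered as a time-dependent covariate in counting-process
  `(start, stop]` form.

For subject *i* with interval adherence class A<sub>ik</sub>, Method B
fits the partial likelihood of
λ<sub>i</sub>(t) = λ<sub>0</sub>(t) · exp(β·A<sub>ik(t)</sub> + γᵀZ<sub>i</sub>),
while Method A replaces A<sub>ik(t)</sub> with the single summary class.
The two coincide exactly when behaviour never changes — and can diverge
dramatically when failing health drives both late non-adherence and
death (survival bias). The package ships a synthetic claims generator
with scenarios (`null`, `causal`, `survival_bias`, `improving_trend`)
that make both situations reproducible, plus cohort selection for
new statin users after an acute coronary syndrome (ACS) hospitalization,
Kaplan-Meier description (ordinary and extended/Simon-Makuch),
summary-vs-interval concordance over time, Schoenfeld-based proportional
hazards diagnostics, VIF collinearity screening, and a sensitivity suite
(binary / three-level / continuous adherence; first- and last-interval
variants; crude and adjusted).

## Worked example

Simulate a 2,000-person cohort in which adherence has **no** causal
effect on death, but declining health suppresses refills shortly before
death, and compare the two measurement approaches:

```r
library(pdcsurv)

cfg <- run_config(
  input = "simulate",
  sim = scenario_preset("survival_bias", n_persons = 2000, seed = 42),
  variants = "headline")
report <- run_pipeline(cfg)
print(report)
#> Adherence-measurement comparison report
#>   cohort retained: 2000
#>   mean summary PDC: 68.7%; optimal adherence: 50.3%
#>   concordance at last completed interval: 85.8%
#>   Method A (summary)  adjusted HR 1.20 (95% CI 0.99-1.44)
#>   Method B (repeated) adjusted HR 0.72 (95% CI 0.60-0.87)
```

Reading the output: about half the cohort reaches optimal adherence
(summary PDC ≥ 80%), and the two classifications agree for 86% of
subjects at the last completed interval. The fixed summary measure finds
no protective association (HR 1.20, CI spanning 1), but the
repeated-measures model reports a *significant* 28% mortality reduction
— entirely spurious here, since the generator's true adherence effect is
zero. Recent adherence is acting as a marker of health, not a cause of
survival. The `causal` scenario shows the complement: a genuine effect
(true HR 0.75 while adherent) that Method B recovers and Method A
attenuates.

Lower-level entry points (`select_cohort()`, `cohort_adherence()`,
`build_counting_process()`, `fit_cox()`, `sensitivity_suite()`, ...) are
documented individually; the methods vignette
(`vignettes/adherence-measurement.Rmd`) explains the coverage algorithm,
the timing and boundary conventions, and what the generator does and
does not emulate.

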