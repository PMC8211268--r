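---
title: "mammosim: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mammosim: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammosim)
```

## The model

mammosim is a per-woman microsimulation of breast-cancer screening and
treatment policy, organised in three levels:

* **Tumor level.** Some women develop a tumor with a latent age of
  symptomatic (clinical) detection, drawn by inverse transform from a
  background clinical-incidence hazard over age and calendar year. Each tumor
  carries an ER/HER2 molecular subtype (age-group-specific proportions), a
  preclinical *sojourn time* — the period in which it is screen-detectable
  but not yet symptomatic — and a stage at detection. Ductal carcinoma in
  situ (DCIS) has its own multistate model (below).
* **Person level.** Each woman has a birth year, an other-cause death age
  sampled from a cohort life table (piecewise-constant hazards within
  single-year bins), a BI-RADS density trajectory assessed at ages 40, 50 and
  65 that never increases with age and is constant after 65, and a scalar
  relative-risk multiplier collapsing person-level risk factors (family
  history, polygenic risk, Down syndrome, ...).
* **Health-system level.** Screening strategies are ordered age segments
  with an interval; mammography sensitivity and specificity are stratified
  by age group, density, interval class and first-vs-subsequent screen.
  Diagnosed women receive adjuvant treatment modalities (chemotherapy,
  endocrine therapy, trastuzumab) by a dissemination model stratified by
  age, stage, subtype and calendar period, filtered by receptor
  eligibility. Treatment acts either by multiplying the breast-cancer death
  hazard (*hazard reduction*) or by curing a fraction of cases
  (*cure fraction*); exactly one mechanism is active per run.

The central design constraint is **counterfactual stability** under common
random numbers: the cohort and every tumor natural history — including the
per-woman uniforms later consumed by stage assignment, treatment and
survival — are generated once, keyed on the master seed, and shared by every
intervention scenario. Screen-level draws are keyed on (woman, screen age),
so nested schedules reuse the same uniform at shared ages. Consequences that
the test suite asserts exactly: a sensitivity-zero screening scenario is a
per-woman no-op; annual screening dominates biennial screening woman by
woman in screens and false positives; and scenario contrasts (deaths
averted, life-years gained) are differences of paired trajectories, not of
independent simulations.

The latent clinical-detection age is deliberately *not* truncated at
other-cause death. That is what makes the counterfactual definition of
**overdiagnosis** computable per woman: a screen-detected cancer is
overdiagnosed exactly when its latent clinical detection would have fallen
after her other-cause death.

## Key quantities

For paired scenarios on one cohort of $n$ women, with $M_\cdot$ the
breast-cancer mortality rate under each of the four intervention arms
(none, screening only, treatment only, both), the package reports:

* deaths averted and life-years gained per 1,000 women (paired per-woman
  differences);
* harm/benefit ratios — mammograms, false positives, benign biopsies per
  death averted or life-year gained — with a non-positive benefit reported
  as *undefined*, never as a silent infinity;
* attribution of the total reduction $M_{none}-M_{both}$ between screening
  and treatment by the two-player Shapley value
  $\varphi_{screen}=\tfrac12[(M_{none}-M_{screen})+(M_{treat}-M_{both})]$
  (and symmetrically for treatment), which is exhaustive
  ($\varphi_{s}+\varphi_{t}=M_{none}-M_{both}$, so shares always sum to
  100%) and splits any negative synergy between the interventions evenly.
  The "several methods" in the literature are not pinned to one formula; we
  chose the Shapley value for its symmetry and exhaustiveness and provide a
  sequential screening-first variant (`method =
  "sequential_screening_first"`) for sensitivity analysis. A percentage
  printed as "63% of the reduction associated with treatment" therefore
  forces a 37% screening share, which is what acceptance target `t2`
  recomputes.

## Tunable parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| linear incidence baseline (1975) | per 100,000/yr | 167 | published anchor of the linear no-screening trend |
| linear annual increment | per 100,000/yr | 0.5 | 0.3% of the baseline, to one decimal |
| sojourn means | years | 1.05–4.55 by subtype × age decade | longer for ER+ and older ages; exponential draws |
| mammography sensitivity | probability | 0.55–0.92 by stratum | rises with age, falls with density |
| specificity | probability | 0.81–0.95 by stratum | first screens less specific |
| stage distribution (screen) | probability | (0.76, 0.20, 0.04) | stage-shifted earlier than clinical (0.55, 0.35, 0.10) |
| baseline bc death hazard | per year | 0.008–0.46 by stratum | ordered local < regional < distant |
| hazard ratios (chemo, endo, trast.) | — | 0.70, 0.70, 0.65 | moderate adjuvant efficacy |
| cure probabilities (cure variant) | — | 0.25, 0.25, 0.30 | complements-product combination |
| benign-biopsy probability given FP | — | 0.5 | harm accounting only |
| DCIS progression fraction | — | 0.3 / 0.5 / 0.8 | the three published submodels |
| DCIS screen sensitivity | — | 0.8 | separate from invasive sensitivity, synthetic |

All values other than the linear-trend anchor are **synthetic and
uncalibrated**: the source models calibrate theirs to surveillance data
(SEER, BCSC) whose estimates are not printed, so only the *stratification
shapes* are reproduced here. The fixture config carries this warning in its
header. A green test therefore establishes the mechanics — sampling
distributions, counterfactual bookkeeping, monotonicities, closed-form
agreement — and not any empirical benefit-harm magnitude.

## What the synthetic generator emulates — and what it does not

Emulated: competing mortality by cohort life table; age-increasing
background incidence; subtype mix shifting ER+ with age; density declining
with age under the stay-or-step-down-one rule; screen detection being
stage-shifted earlier; dissemination improving over calendar periods and
dropping at old age. Not emulated: calendar trends in underlying incidence
beyond the linear variant; correlation between sojourn and stage-dwell times
(sampled independently — the source models' joint behaviour is not
published); density-incidence interaction (an optional multiplier exists,
default off, because no quantitative link is printed); second primaries and
recurrences; radiation-induced risk; comorbidity-specific life tables beyond
a scalar hazard multiplier.

## Numerical choices

* **Inverse-transform sampling everywhere.** Piecewise-constant hazards on
  single-year bins give closed-form inverses, so samplers can be tested
  against exponential medians/tails exactly; a day-grid discrete oracle
  agrees with the continuous sampler at Kolmogorov–Smirnov distance < 0.01.
* **Substream seeds** are derived from the master seed by a 31-bit
  multiply-add hash of (purpose, keys), kept below $2^{48}$ so double
  arithmetic is exact, then passed to `set.seed()`. Keyed (not sequential)
  substreams are what make stream isolation hold: adding a scenario or
  purpose cannot shift another's draws. Draws at the cohort/natural-history
  level are vectorised per purpose (woman *i* takes element *i*), which is a
  deliberate deviation from per-woman sequential generators for speed; every
  consequence the common-random-number contract needs is asserted in tests.
* **Density transition solve.** The stay-or-step-down-one rule makes the
  marginal-matching problem triangular; it is solved from category `d`
  downwards, infeasible marginals are reported with the offending category,
  and stay probabilities for empty categories are vacuously 1.
* **Half-open conventions.** Age groups are `[lo, hi)` with the top group
  unbounded; the preclinical detection window is `[onset, clinical age)` — a
  screen exactly at the clinical age is moot because symptomatic detection
  occurs first; periods are half-open year intervals, with years before the
  earliest period mapped onto it.
* **Interval classes** for performance lookup derive from the realised gap
  since the previous attended screen (< 1.5 y annual, < 2.5 y biennial, else
  triennial/infrequent); first screens use the first-screen column.
* **Sojourn truncation.** When a drawn sojourn would push the preclinical
  onset below age 0, onset is floored at 0 and the sojourn truncated.
* **Degenerate inputs.** Undefined ratios (zero benefit), no screen-detected
  DCIS, and all-zero DCIS exit rates are first-class reported conditions,
  not NaNs or silent defaults.

## Design decisions that were genuinely open

* **Model-M linear incidence and age.** Whether the linear variant is
  age-specific is not stated; the trend is age-independent by default, with
  an optional age-profile multiplier table (documented, off by default).
* **Gompertz growth variant.** The published family is named but not the
  formula; we use
  $d(t) = d_{max}(d_0/d_{max})^{\exp(-\gamma\,\max(0, t-\mathrm{lag}))}$
  with defaults $d_0 = 2$ mm, $d_{max} = 128$ mm, $\gamma = 0.5$/yr, lag
  0.5 y, screen-detectable at 5 mm and clinically detectable at 20 mm, and a
  closed-form threshold-crossing inverse checked against bisection. It is a
  documented stand-in.
* **Three stage mechanisms** (table, dwell-time, growth-threshold) are
  provided because the model family uses both stage tables and
  dwell/growth-rate inputs; exactly one is active per run.
* **Cure-model non-cured cases** keep unmodified baseline survival (the
  source behaviour is unstated).
* **Screen-detected DCIS is treated as fully excised** (progression halts),
  the reading most consistent with "in the absence of biopsy or complete
  excision"; noted as an assumption.
* **False positives do not affect later attendance** (unstated in the
  source; kept independent).
* **Down-syndrome-style profiles** are expressed as `risk_multiplier = 0.25`
  with an elevated other-cause hazard multiplier, matching the "~75% lower
  breast-cancer risk, much shorter life expectancy" description, rather than
  a bespoke pathway.

## Worked example

```{r example, eval = FALSE}
strat <- screening_strategy("biennial 50-74",
  data.frame(start_age = 50, end_age = 74, interval = 2))
run <- run_scenarios(list(
  n = 2000, birth_year = 1960, seed = 3,
  scenarios = list(
    none        = list(strategy = NULL,  treatment_on = FALSE),
    screen_only = list(strategy = strat, treatment_on = FALSE),
    treat_only  = list(strategy = NULL,  treatment_on = TRUE),
    both        = list(strategy = strat, treatment_on = TRUE))))
run$summary
compare_scenarios(run$results$both$log, run$results$none$log)
```

## Known limitations

Desk-scale only (one CPU, in-memory cohorts); no calibration machinery — the
package consumes parameter tables, it does not estimate them; no costs,
no toxicity outputs, no race-specific parameterizations, no MRI/tomosynthesis
modality logic; the per-modality (3+-player) attribution split is exposed as
machinery but its published computation method is unspecified, so no
published split is reproduced. None of the published headline magnitudes
(overdiagnosis percentages, deaths-averted tables) are asserted anywhere:
they depend on six independently calibrated parameter sets that are not
public. Every number the documentation shows is produced by the package's
own tests or example code.
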