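# mammosim

A multilevel microsimulation of breast-cancer natural history, mammography
screening, and adjuvant treatment, for benefit–harm analysis of screening
policies at desk scale.

Policy models in this field answer questions like: *how many breast-cancer
deaths does biennial screening from 50 to 74 avert per 1,000 women, at the
cost of how many false positives and how much overdiagnosis — and how much
of the observed mortality decline is attributable to screening versus
treatment?* mammosim implements the full machinery for such questions as a
per-woman simulator with three levels:

- **tumor**: latent symptomatic-detection age from a background incidence
  hazard (tabular, or the linear no-screening trend anchored at 167 per
  100,000 in 1975 rising 0.5 per 100,000 per year), ER/HER2 subtype,
  exponential preclinical sojourn (the screen-detectable window), stage at
  detection (table, stage-dwell, or Gompertz-growth variants), and a DCIS
  multistate model (undetectable → preclinical → {clinical DCIS, invasive,
  regressed}) with the 30/50/80% progression submodels;
- **person**: birth cohort, other-cause death from a life table, BI-RADS
  density trajectory (never increasing across ages 40/50/65), scalar
  relative-risk profiles;
- **health system**: screening strategies (age segments × interval,
  full-adherence or empirical dissemination), sensitivity/specificity
  stratified by age × density × interval × first-vs-subsequent screen,
  treatment dissemination by age × stage × subtype × period, and efficacy by
  hazard reduction or cure fraction.

Scenarios run under **common random numbers**: natural histories are
generated once and shared, so contrasts (deaths averted, life-years gained,
overdiagnosis) are paired per woman. Overdiagnosis uses the counterfactual
definition — a screen-detected cancer whose latent clinical detection falls
after the woman's other-cause death. Mortality reduction is attributed
between screening and treatment with a two-player Shapley decomposition
whose shares always sum to 100%.

All parameter tables ship as *documented synthetic defaults*: strata shapes
follow the standard input taxonomy, values are plausible but uncalibrated
(see the methods vignette, `vignettes/mammosim-methods.Rmd`).

## Worked example

```r
library(mammosim)
strat <- screening_strategy("biennial 50-74",
  data.frame(start_age = 50, end_age = 74, interval = 2))
run <- run_scenarios(list(
  n = 2000, birth_year = 1960, seed = 3,
  scenarios = list(
    none        = list(strategy = NULL,  treatment_on = FALSE),
    screen_only = list(strategy = strat, treatment_on = FALSE),
    treat_only  = list(strategy = NULL,  treatment_on = TRUE),
    both        = list(strategy = strat, treatment_on = TRUE))))
subset(run$summary, scenario == "both")
#>    scenario              output per_1000
#> 25     both             screens  10771.0
#> 26     both     false_positives    901.0
#> 27     both     benign_biopsies    475.0
#> 28     both    interval_cancers      6.0
#> 29     both     screen_detected     56.0
#> 30     both clinically_detected     72.5
#> 31     both       overdiagnosed      4.0
#> 32     both           bc_deaths     31.5
```

Per 1,000 women followed for life under biennial screening with treatment:
10,771 mammograms, 901 false positives, 56 screen-detected and 72.5
clinically detected cancers, 4 overdiagnosed cases, and 31.5 breast-cancer
deaths — versus 43.5 deaths with neither intervention (`none` arm), so 12
deaths averted per 1,000. The four arms feed the attribution:

```r
at <- run_attribution(list(n = 2000, birth_year = 1960, seed = 3,
                           strategy = strat))
round(unlist(at$attribution), 1)
#> total_reduction_pct screening_share_pct treatment_share_pct
#>                26.1                41.7                58.3
#>          phi_screen           phi_treat
#>               375.0               525.0
```

Under the synthetic defaults, the simulated mortality reduction splits ~42%
screening / ~58% treatment. (These magnitudes are illustrative: the
defaults are deliberately uncalibrated.)

There is also a CLI (`inst/cli/mammosim`): `params init`, `params
validate`, `run`, `attribute`, `dcis-sweep`, `report`.

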