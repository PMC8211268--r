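Package: mammosim
Title: Multilevel Breast-Cancer Screening and Treatment Microsimulation
Version: 0.1.0
Authors@R: person("Mammosim", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A per-woman microsimulation of breast-cancer natural history,
    mammography screening, and adjuvant treatment for benefit-harm analysis
    of screening policies. Simulates counterfactual-stable life histories
    (other-cause mortality, BI-RADS density trajectories, tumor inception,
    ER/HER2 subtype, preclinical sojourn, stage progression), screening
    strategies with stratified test performance, treatment dissemination with
    hazard-reduction or cure-fraction efficacy, and a DCIS multistate model
    with optional regression. Outputs include overdiagnosis, deaths averted,
    life-years gained, harm/benefit ratios, and Shapley attribution of
    mortality reduction between screening and treatment, computed under
    common random numbers so scenario contrasts are low-variance. All
    parameter tables ship as documented synthetic defaults.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
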