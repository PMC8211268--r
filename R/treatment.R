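# Treatment: subtype/stage-specific adjuvant dissemination, survival under
# hazard-reduction or cure-fraction efficacy, and death resolution against
# other-cause mortality. Local therapy (surgery) is universal and implicit.

#' Assign adjuvant treatment modalities at diagnosis
#'
#' Each modality (chemotherapy, endocrine therapy, trastuzumab) is drawn
#' independently with its dissemination probability for the (age group,
#' stage, subtype, calendar period) stratum, then filtered by receptor
#' eligibility: endocrine therapy requires an ER-positive tumor, trastuzumab
#' a HER2-positive one.
#'
#' @param params a `mammosim_params` object
#' @param subtype one of [SUBTYPES]
#' @param stage one of [STAGES]
#' @param age age at diagnosis
#' @param year calendar year at diagnosis
#' @param u3 named (or ordered) uniforms for (chemotherapy, endocrine,
#'   trastuzumab)
#' @return character vector of assigned modalities (possibly empty)
#' @export
assign_treatment <- function(params, subtype, stage, age, year, u3) {
  er_pos <- startsWith(subtype, "ER+")
  her2_pos <- endsWith(subtype, "HER2+")
  eligible <- c(chemotherapy = TRUE, endocrine = er_pos,
                trastuzumab = her2_pos)
  got <- character()
  for (k in seq_along(MODALITIES)) {
    m <- MODALITIES[k]
    if (!eligible[[m]]) next
    p <- dissemination_prob_of(params, age, stage, subtype, year, m)
    if (u3[k] < p) got <- c(got, m)
  }
  got
}

#' Sample breast-cancer survival after diagnosis
#'
#' Baseline breast-cancer-specific survival is exponential with the stratum
#' hazard (age group at diagnosis, stage, subtype). Under the
#' `hazard_reduction` mechanism the hazard is multiplied by the product of
#' the assigned modalities' hazard ratios. Under the `cure_fraction`
#' mechanism the case is cured with probability `1 - prod(1 - c_m)` over
#' assigned modalities (independent-complements combination); non-cured cases
#' keep unmodified baseline survival.
#'
#' The survival quantile `u_survival` is drawn once per woman at natural-
#' history time and shared across scenarios, so treatment and detection-mode
#' contrasts act on a fixed quantile — the per-woman counterfactual pairing
#' that makes deaths-averted low-variance.
#'
#' @param params a `mammosim_params` object
#' @param detection list/row with `age` and `stage`
#' @param subtype one of [SUBTYPES]
#' @param modalities assigned modalities (character, possibly empty)
#' @param u_survival survival quantile in (0,1)
#' @param u_cure cure quantile in (0,1)
#' @param mechanism override for `params$efficacy_mechanism`
#' @return list: `cured` (flag), `bc_death_age` (`Inf` when cured)
#' @export
sample_bc_survival <- function(params, detection, subtype, modalities,
                               u_survival, u_cure,
                               mechanism = params$efficacy_mechanism) {
  h0 <- survival_hazard_of(params, detection$age, detection$stage, subtype)
  ef <- params$efficacy
  i <- match(modalities, ef$modality)
  if (mechanism == "cure_fraction") {
    p_cure <- if (length(i)) 1 - prod(1 - ef$cure_probability[i]) else 0
    if (u_cure < p_cure) return(list(cured = TRUE, bc_death_age = Inf))
    h <- h0
  } else {
    hr <- if (length(i)) prod(ef$hazard_ratio[i]) else 1
    if (any(ef$hazard_ratio[i] <= 0 | ef$hazard_ratio[i] > 1))
      stop("hazard ratio outside (0,1]")
    h <- h0 * hr
  }
  t_surv <- if (h <= 0) Inf else -log(1 - u_survival) / h
  list(cured = FALSE, bc_death_age = detection$age + t_surv)
}

#' Resolve a woman's death age and cause
#'
#' Death occurs at the earlier of the breast-cancer death age and the
#' other-cause death age; cured or never-diagnosed women die of other causes.
#'
#' @param other_cause_death_age the woman's other-cause death age
#' @param bc_death_age breast-cancer death age, or `Inf`/`NA` for
#'   cured/undiagnosed
#' @return list: `death_age`, `cause` (`"breast_cancer"` or `"other"`)
#' @export
resolve_death <- function(other_cause_death_age, bc_death_age = Inf) {
  if (is.na(bc_death_age)) bc_death_age <- Inf
  if (bc_death_age < other_cause_death_age) {
    list(death_age = bc_death_age, cause = "breast_cancer")
  } else {
    list(death_age = other_cause_death_age, cause = "other")
  }
}

#' Diagnose-treat-survive pipeline for one woman
#'
#' @param woman cohort row; `tumor` natural-history row; `detection` the
#'   [screen_woman()] detection record
#' @param tumor natural-history row (carries the reserved uniforms)
#' @param detection detection record (`mode`, `age`, `stage`)
#' @param params a `mammosim_params` object
#' @param treatment_on if `FALSE`, no modalities are assigned (background
#'   survival) — the "no treatment" scenario arm
#' @return list: `modalities`, `cured`, `bc_death_age`, `death_age`, `cause`
#' @export
treat_and_resolve <- function(woman, tumor, detection, params,
                              treatment_on = TRUE) {
  if (detection$mode == "none") {
    d <- resolve_death(woman$other_cause_death_age, Inf)
    return(list(modalities = character(), cured = FALSE, bc_death_age = Inf,
                death_age = d$death_age, cause = d$cause))
  }
  year <- woman$birth_year + detection$age
  modalities <- if (treatment_on) {
    assign_treatment(params, tumor$subtype, detection$stage, detection$age,
                     year, c(tumor$u_chemo, tumor$u_endocrine,
                             tumor$u_trastuzumab))
  } else character()
  s <- sample_bc_survival(params, detection, tumor$subtype, modalities,
                          tumor$u_survival, tumor$u_cure)
  d <- resolve_death(woman$other_cause_death_age, s$bc_death_age)
  list(modalities = modalities, cured = s$cured,
       bc_death_age = s$bc_death_age, death_age = d$death_age,
       cause = d$cause)
}
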