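# Output analysis: overdiagnosis classification, per-1,000 counters,
# age-adjusted rates, scenario comparison, harm/benefit ratios, Shapley
# attribution of mortality reduction, and ensemble summaries.

#' Classify one case as overdiagnosed
#'
#' A screen-detected cancer is overdiagnosed when it would never have been
#' diagnosed in the woman's lifetime absent screening: the latent clinical
#' detection age exceeds the other-cause death age. Clinically detected
#' cases are never overdiagnosed by definition.
#'
#' @param mode detection mode (`"screen"`, `"clinical"`, `"none"`)
#' @param latent_clinical_age latent symptomatic-detection age
#' @param other_cause_death_age other-cause death age
#' @return logical flag
#' @export
classify_overdiagnosis <- function(mode, latent_clinical_age,
                                   other_cause_death_age) {
  if (mode != "screen") return(FALSE)
  if (is.na(latent_clinical_age))
    stop("screen-detected case with missing latent clinical age")
  latent_clinical_age > other_cause_death_age
}

#' Directly age-standardize a set of age-group rates
#'
#' @param rates named (or ordered) numeric vector of age-group rates
#' @param weights standard-population weights over the same groups, summing
#'   to 1
#' @return the weighted (directly standardized) rate
#' @export
age_adjust <- function(rates, weights) {
  if (length(rates) != length(weights))
    stop("rates and weights cover different numbers of age groups")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  sum(rates * weights)
}

#' Compare a scenario against its paired comparator
#'
#' Requires per-woman logs from the *same* cohort under common random
#' numbers. Deaths averted is the difference in breast-cancer death counts;
#' life-years gained is the sum of per-woman death-age differences. Both are
#' reported per 1,000 women. QALYs apply an optional utility weight per
#' life-year.
#'
#' @param scenario,comparator per-woman data.frames with columns `id`,
#'   `death_age`, `cause`
#' @param utility scalar utility weight per life-year gained (QALY proxy)
#' @return list: `deaths_averted_per_1000`, `life_years_gained_per_1000`,
#'   `qaly_gained_per_1000`
#' @export
compare_scenarios <- function(scenario, comparator, utility = 1) {
  if (nrow(scenario) != nrow(comparator) ||
      !identical(scenario$id, comparator$id))
    stop("scenario and comparator logs are not the same paired cohort")
  n <- nrow(scenario)
  da <- (sum(comparator$cause == "breast_cancer") -
           sum(scenario$cause == "breast_cancer")) / n * 1000
  lyg <- sum(scenario$death_age - comparator$death_age) / n * 1000
  list(deaths_averted_per_1000 = da,
       life_years_gained_per_1000 = lyg,
       qaly_gained_per_1000 = lyg * utility)
}

#' Harm/benefit ratio
#'
#' Harms (mammograms, false positives, benign biopsies) per unit benefit
#' (death averted, life-year gained). A non-positive benefit makes the ratio
#' undefined; it is reported as such, never as a silent infinity.
#'
#' @param harm harm counter (>= 0)
#' @param benefit benefit counter
#' @return list: `ratio` (`NA` when undefined), `defined` flag
#' @examples
#' harm_benefit_ratio(920, 6.7)  # 137.31 false positives per death averted
#' @export
harm_benefit_ratio <- function(harm, benefit) {
  if (benefit <= 0) {
    return(list(ratio = NA_real_, defined = FALSE,
                note = "benefit is not positive: ratio undefined"))
  }
  list(ratio = harm / benefit, defined = TRUE)
}

#' Attribute mortality reduction between screening and treatment
#'
#' Given breast-cancer mortality rates in a reference year under the four
#' paired scenarios (no intervention, screening only, treatment only, both),
#' computes the total reduction and splits it with the two-player Shapley
#' value, which allocates the screening-treatment interaction (possibly
#' negative synergy) evenly:
#' `phi_screen = ((M_none - M_screen) + (M_treat - M_both)) / 2`, and
#' symmetrically for treatment. Shares are percentages of the total
#' reduction and always sum to 100. A sequential screening-first
#' decomposition is available for sensitivity analysis.
#'
#' @param m_none,m_screen_only,m_treat_only,m_both mortality rates (same
#'   units, e.g. per 100,000, age-adjusted within one calendar year)
#' @param method `"shapley"` (default) or `"sequential_screening_first"`
#' @return list: `total_reduction_pct`, `screening_share_pct`,
#'   `treatment_share_pct`, `phi_screen`, `phi_treat`
#' @examples
#' attribute_reduction(60, 50, 45, 40)  # shares 37.5 / 62.5
#' @export
attribute_reduction <- function(m_none, m_screen_only, m_treat_only, m_both,
                                method = c("shapley",
                                           "sequential_screening_first")) {
  method <- match.arg(method)
  if (m_none <= 0) stop("mortality without intervention must be > 0")
  total <- m_none - m_both
  if (total <= 0) stop("zero or negative total reduction: shares undefined")
  if (method == "shapley") {
    phi_s <- ((m_none - m_screen_only) + (m_treat_only - m_both)) / 2
    phi_t <- ((m_none - m_treat_only) + (m_screen_only - m_both)) / 2
  } else {
    phi_s <- m_none - m_screen_only
    phi_t <- m_screen_only - m_both
  }
  list(total_reduction_pct = 100 * total / m_none,
       screening_share_pct = 100 * phi_s / total,
       treatment_share_pct = 100 * phi_t / total,
       phi_screen = phi_s, phi_treat = phi_t)
}

#' Summarize outputs across an ensemble of parameter variants
#'
#' Mirrors multi-model reporting practice: every output is given as the
#' average and the inclusive range across variants.
#'
#' @param results list of named numeric vectors/lists (one per variant), all
#'   with the same fields
#' @return data.frame with columns `output`, `mean`, `min`, `max`
#' @export
ensemble_summary <- function(results) {
  if (!length(results)) stop("ensemble_summary: no results supplied")
  fields <- names(results[[1]])
  rows <- lapply(fields, function(f) {
    v <- vapply(results, function(r) as.numeric(r[[f]]), numeric(1))
    data.frame(output = f, mean = mean(v), min = min(v), max = max(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Age-adjusted breast-cancer mortality rate in one calendar year
#'
#' Deaths per 100,000 woman-years within `[year, year + 1)`, computed per
#' standard-population age group and directly standardized. Person-time is
#' the time each woman is alive during the year.
#'
#' @param log per-woman data.frame with `birth_year`, `death_age`, `cause`
#' @param year calendar year
#' @param params a `mammosim_params` object (standard population weights)
#' @param adjust directly standardize (default) or return the crude rate
#' @return rate per 100,000 woman-years
#' @export
mortality_rate_in_year <- function(log, year, params, adjust = TRUE) {
  age_start <- year - log$birth_year          # age at the start of `year`
  py <- pmax(pmin(log$death_age - age_start, 1), 0)
  at_risk <- py > 0
  death_year <- log$birth_year + log$death_age
  died_bc <- log$cause == "breast_cancer" & death_year >= year &
    death_year < year + 1
  grp <- age_group_of(pmax(age_start, 0), "std")
  sp <- params$standard_population
  rates <- vapply(sp$age_group, function(g) {
    i <- at_risk & grp == g
    pt <- sum(py[i])
    if (pt <= 0) 0 else sum(died_bc[i]) / pt * 1e5
  }, numeric(1))
  if (adjust) age_adjust(rates, sp$weight) else {
    pt <- sum(py[at_risk])
    if (pt <= 0) 0 else sum(died_bc[at_risk]) / pt * 1e5
  }
}
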