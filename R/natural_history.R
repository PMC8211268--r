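# Tumor level, absent screening: latent clinical-detection age, subtype,
# preclinical sojourn, stage-at-detection machinery (table, dwell-time, or
# Gompertz-growth variants). The latent clinical-detection age is generated
# even when it falls after other-cause death: the counterfactual definition
# of overdiagnosis needs it.

# per-100,000 incidence hazard for one woman over single-year age bins 0-119,
# calendar year = birth_year + age (continuous ages, half-open year bins)
incidence_hazards <- function(params, birth_year, risk_multiplier = 1,
                              density_multiplier = 1) {
  ages <- 0:119
  rates <- background_rate(params, ages, birth_year + ages)
  rates / 1e5 * risk_multiplier * density_multiplier
}

#' Sample the latent age at symptomatic (clinical) detection
#'
#' Inverse-transform draw from the cumulative background clinical-incidence
#' hazard over age (calendar year tracking `birth_year + age`), scaled by the
#' woman's relative-risk multiplier and an optional density multiplier.
#' Returns `NA` ("no tumor ever") when the draw exceeds age 120. The draw is
#' deliberately *not* truncated at other-cause death: the latent date is what
#' makes per-woman overdiagnosis classification possible.
#'
#' @param params a `mammosim_params` object
#' @param birth_year calendar year of birth
#' @param risk_multiplier relative breast-cancer incidence (> 0)
#' @param u uniform draw(s); vectorised
#' @param density_multiplier optional per-category incidence multiplier
#'   (default 1; the quantitative density-incidence link is left off by
#'   default)
#' @return latent clinical-detection age(s), `NA` when none
#' @export
sample_clinical_incidence <- function(params, birth_year, risk_multiplier = 1,
                                      u, density_multiplier = 1) {
  h <- incidence_hazards(params, birth_year, risk_multiplier,
                         density_multiplier)
  a <- pch_inverse(u, h)
  a[a >= 120] <- NA_real_
  a
}

#' Draw an ER/HER2 molecular subtype
#'
#' @param params a `mammosim_params` object
#' @param age_at_clinical latent clinical-detection age (picks the age group)
#' @param u uniform draw
#' @return one of [SUBTYPES]
#' @export
assign_subtype <- function(params, age_at_clinical, u) {
  pr <- subtype_prob_vector(params, age_at_clinical)
  SUBTYPES[pmin(findInterval(u, cumsum(pr), left.open = TRUE) + 1L, 4L)]
}

#' Draw a preclinical sojourn time
#'
#' Exponential with the stratum mean (subtype by age decade) by default;
#' `mode = "fixed"` returns the mean itself (useful as a deterministic
#' oracle). The preclinical onset age is the clinical-detection age minus the
#' sojourn, floored at 0 with the sojourn truncated accordingly.
#'
#' @param params a `mammosim_params` object
#' @param subtype one of [SUBTYPES]
#' @param age_at_clinical latent clinical-detection age (picks the decade)
#' @param u uniform draw
#' @param mode `"exponential"` or `"fixed"`
#' @return sojourn in years (> 0)
#' @export
sample_sojourn <- function(params, subtype, age_at_clinical, u,
                           mode = c("exponential", "fixed")) {
  mode <- match.arg(mode)
  m <- sojourn_mean_of(params, subtype, age_at_clinical)
  if (m <= 0) stop("sojourn mean must be > 0")
  if (mode == "fixed") m else -m * log(1 - u)
}

#' Draw a stage at detection from the tabulated distribution
#'
#' @param params a `mammosim_params` object
#' @param mode `"screen"` or `"clinical"`
#' @param age age at detection (picks the age group)
#' @param u uniform draw; using the *same* per-woman uniform for the screen
#'   and clinical lookups couples the two quantiles, so a screen-detected
#'   stage is never later than the clinical stage it replaces when the screen
#'   distribution stochastically dominates
#' @return one of [STAGES]
#' @export
assign_stage <- function(params, mode, age, u) {
  pr <- stage_dist_of(params, mode, age)
  STAGES[pmin(findInterval(u, cumsum(pr), left.open = TRUE) + 1L, 3L)]
}

#' Stage progression by exponential dwell times
#'
#' In the dwell-time variant a tumor enters `local` at preclinical onset,
#' dwells an exponential time with the local mean, moves to `regional`,
#' dwells again, then `distant`.
#'
#' @param onset_age preclinical onset age
#' @param dwell_means data.frame with columns `stage` (`"local"`,
#'   `"regional"`) and `mean_years` (> 0)
#' @param u2 two uniforms (local and regional dwell draws)
#' @return named vector of entry ages `(local, regional, distant)`, strictly
#'   increasing
#' @export
progress_stage_dwell <- function(onset_age, dwell_means, u2) {
  m <- dwell_means$mean_years[match(c("local", "regional"), dwell_means$stage)]
  if (any(is.na(m)) || any(m <= 0)) stop("dwell means must be > 0 for local and regional")
  d1 <- -m[1] * log(1 - u2[1])
  d2 <- -m[2] * log(1 - u2[2])
  c(local = onset_age, regional = onset_age + d1,
    distant = onset_age + d1 + d2)
}

#' Stage occupied at a given age (dwell-time variant)
#'
#' @param entry_ages output of [progress_stage_dwell()]
#' @param t age queried (must be >= onset)
#' @return one of [STAGES]
#' @export
stage_at <- function(entry_ages, t) {
  if (t < entry_ages["local"]) stop("stage query before preclinical onset")
  STAGES[findInterval(t, entry_ages)]
}

#' Gompertz tumor diameter with growth lag
#'
#' `d(t) = d_max * (d_0 / d_max) ^ exp(-rate * max(0, t - lag))`: diameter
#' sits at `d_0` through the lag, then grows monotonically towards the
#' asymptote `d_max`.
#'
#' @param t years since preclinical inception (vectorised)
#' @param gp list with `d0_mm`, `dmax_mm`, `rate` (per year), `lag_years`
#' @return diameter in mm
#' @export
gompertz_diameter <- function(t, gp) {
  if (gp$d0_mm <= 0 || gp$dmax_mm <= gp$d0_mm || gp$rate <= 0)
    stop("invalid growth parameters: need 0 < d0 < dmax and rate > 0")
  if (any(t < 0)) stop("t must be >= 0")
  gp$dmax_mm * (gp$d0_mm / gp$dmax_mm)^exp(-gp$rate * pmax(0, t - gp$lag_years))
}

#' Closed-form threshold-crossing time for the lagged Gompertz curve
#'
#' Inverts [gompertz_diameter()]:
#' `t = lag + log(log(dmax/d0) / log(dmax/threshold)) / rate`.
#'
#' @param threshold_mm diameter threshold in `(d0, dmax)`
#' @param gp growth parameter list (see [gompertz_diameter()])
#' @return years since inception at which the diameter reaches the threshold
#' @export
gompertz_crossing_time <- function(threshold_mm, gp) {
  if (threshold_mm <= gp$d0_mm || threshold_mm >= gp$dmax_mm)
    stop("threshold must lie strictly between d0 and dmax")
  gp$lag_years +
    log(log(gp$dmax_mm / gp$d0_mm) / log(gp$dmax_mm / threshold_mm)) / gp$rate
}

#' Simulate counterfactual-stable tumor natural histories for a cohort
#'
#' For each woman, draws whether and when a tumor would surface clinically in
#' the absence of screening, its subtype, preclinical sojourn (hence onset
#' age), and the per-woman uniforms later consumed by stage assignment,
#' treatment dissemination, and survival. Everything here is keyed on
#' `(seed, purpose)` substreams independent of any scenario, so the returned
#' table — including the stored uniforms — is bitwise identical no matter
#' which screening or treatment scenario consumes it.
#'
#' @param cohort a [build_cohort()] data.frame
#' @param params a `mammosim_params` object
#' @param seed master seed (use the same seed as the cohort)
#' @param sojourn_mode `"exponential"` (default) or `"fixed"`
#' @param stage_mechanism `"table"` (default), `"dwell"`, or `"growth"`;
#'   exactly one is active per run
#' @return data.frame, one row per woman, with `has_tumor`,
#'   `clinical_detection_age`, `sojourn_years`, `preclinical_onset_age`,
#'   `subtype`, `stage_at_clinical`, dwell entry ages, and reserved uniforms
#'   `u_stage`, `u_chemo`, `u_endocrine`, `u_trastuzumab`, `u_cure`,
#'   `u_survival`
#' @export
simulate_natural_history <- function(cohort, params, seed,
                                     sojourn_mode = c("exponential", "fixed"),
                                     stage_mechanism = c("table", "dwell",
                                                         "growth")) {
  sojourn_mode <- match.arg(sojourn_mode)
  stage_mechanism <- match.arg(stage_mechanism)
  n <- nrow(cohort)
  u_inc <- stream_runif(n, seed, "nh", "incidence")
  u_sub <- stream_runif(n, seed, "nh", "subtype")
  u_soj <- stream_runif(n, seed, "nh", "sojourn")
  u_dw1 <- stream_runif(n, seed, "nh", "dwell_local")
  u_dw2 <- stream_runif(n, seed, "nh", "dwell_regional")

  clin_age <- sample_clinical_incidence(
    params, cohort$birth_year[1], cohort$risk_multiplier[1], u_inc)
  has <- !is.na(clin_age)

  subtype <- rep(NA_character_, n)
  sojourn <- rep(NA_real_, n)
  onset <- rep(NA_real_, n)
  stage_clin <- rep(NA_character_, n)
  ent_reg <- rep(NA_real_, n)
  ent_dis <- rep(NA_real_, n)

  u_stage <- stream_runif(n, seed, "nh", "stage")
  if (stage_mechanism == "growth") {
    # growth variant: sojourn is the (deterministic) time for the diameter to
    # grow from the screen-detectable to the clinically detectable threshold
    gp <- params$growth_params
    growth_sojourn <- gompertz_crossing_time(gp$clinical_threshold_mm, gp) -
      gompertz_crossing_time(gp$screen_threshold_mm, gp)
  }
  for (i in which(has)) {
    subtype[i] <- assign_subtype(params, clin_age[i], u_sub[i])
    s <- if (stage_mechanism == "growth") growth_sojourn else
      sample_sojourn(params, subtype[i], clin_age[i], u_soj[i],
                     mode = sojourn_mode)
    onset[i] <- max(clin_age[i] - s, 0)
    sojourn[i] <- clin_age[i] - onset[i]
    if (stage_mechanism == "dwell") {
      ent <- progress_stage_dwell(onset[i], params$dwell_means,
                                  c(u_dw1[i], u_dw2[i]))
      ent_reg[i] <- ent["regional"]
      ent_dis[i] <- ent["distant"]
      stage_clin[i] <- stage_at(ent, clin_age[i])
    } else if (stage_mechanism == "growth") {
      stage_clin[i] <- stage_from_diameter(gp$clinical_threshold_mm)
    } else {
      stage_clin[i] <- assign_stage(params, "clinical", clin_age[i],
                                    u_stage[i])
    }
  }

  out <- data.frame(
    id = cohort$id,
    has_tumor = has,
    clinical_detection_age = clin_age,
    sojourn_years = sojourn,
    preclinical_onset_age = onset,
    subtype = subtype,
    stage_at_clinical = stage_clin,
    entry_regional = ent_reg,
    entry_distant = ent_dis,
    u_stage = u_stage,
    u_chemo = stream_runif(n, seed, "nh", "chemo"),
    u_endocrine = stream_runif(n, seed, "nh", "endocrine"),
    u_trastuzumab = stream_runif(n, seed, "nh", "trastuzumab"),
    u_cure = stream_runif(n, seed, "nh", "cure"),
    u_survival = stream_runif(n, seed, "nh", "survival"),
    stringsAsFactors = FALSE
  )
  attr(out, "stage_mechanism") <- stage_mechanism
  out
}

# growth variant: time from screen-detectability (d0 threshold is inception)
# to the clinical threshold defines the clinically visible size at symptoms
growth_screen_offset <- function(params) {
  gompertz_crossing_time(params$growth_params$screen_threshold_mm,
                         params$growth_params)
}

# synthetic size-to-stage map for the growth variant
stage_from_diameter <- function(d_mm) {
  ifelse(d_mm < 15, "local", ifelse(d_mm < 40, "regional", "distant"))
}
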