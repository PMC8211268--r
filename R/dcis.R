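# DCIS multistate natural history: undetectable lesion -> (progression gate)
# -> preclinical screen-detectable DCIS -> {clinical DCIS, invasive, regressed}
# by competing exponential exits, censored at other-cause death. Screen-
# detected DCIS is treated as fully excised: progression halts at detection,
# and overdiagnosis is judged against the counterfactual exit.

#' Define DCIS multistate parameters
#'
#' @param progression_fraction probability an undetectable lesion ever
#'   becomes preclinical screen-detectable; the published submodels use 0.3,
#'   0.5, and 0.8, but any value in (0, 1] is accepted
#' @param rate_to_clinical per-year exit rate, preclinical -> clinical DCIS
#' @param rate_to_invasive per-year exit rate, preclinical -> invasive cancer
#' @param rate_regress per-year exit rate, preclinical -> no breast cancer
#'   (0 prohibits regression)
#' @param onset_rate per-year rate of undetectable-lesion onset (synthetic
#'   default; the source models calibrate this, so no published value exists)
#' @param onset_min_age age before which no lesions arise
#' @param latency_mean_years mean of the exponential undetectable ->
#'   preclinical waiting time, conditional on progressing
#' @param dcis_sensitivity per-screen probability a preclinical DCIS lesion
#'   is detected (separate from invasive sensitivity; synthetic default 0.8)
#' @return an object of class `mammosim_dcis_params`
#' @export
dcis_parameters <- function(progression_fraction = 0.5,
                            rate_to_clinical = 0.2,
                            rate_to_invasive = 0.3,
                            rate_regress = 0,
                            onset_rate = 0.002,
                            onset_min_age = 25,
                            latency_mean_years = 2,
                            dcis_sensitivity = 0.8) {
  if (progression_fraction <= 0 || progression_fraction > 1)
    stop("progression_fraction must be in (0, 1]")
  rates <- c(rate_to_clinical, rate_to_invasive, rate_regress, onset_rate)
  if (any(rates < 0) || any(!is.finite(rates))) stop("rates must be finite and >= 0")
  if (rate_to_clinical + rate_to_invasive + rate_regress <= 0)
    stop("all preclinical exit rates are zero: the preclinical state would be absorbing")
  structure(list(progression_fraction = progression_fraction,
                 rate_to_clinical = rate_to_clinical,
                 rate_to_invasive = rate_to_invasive,
                 rate_regress = rate_regress,
                 onset_rate = onset_rate,
                 onset_min_age = onset_min_age,
                 latency_mean_years = latency_mean_years,
                 dcis_sensitivity = dcis_sensitivity),
            class = "mammosim_dcis_params")
}

#' Simulate DCIS natural histories for a cohort
#'
#' Lesion onset is exponential beyond `onset_min_age`; a Bernoulli gate with
#' the progression fraction decides whether the lesion ever becomes
#' preclinical screen-detectable; the preclinical state is left by competing
#' exponential exits to clinical DCIS, invasive cancer, or regression.
#' Histories record both the realised (death-censored) exit and the latent
#' counterfactual exit, which overdiagnosis classification needs.
#'
#' @param cohort a [build_cohort()] data.frame
#' @param dp a [dcis_parameters()] object
#' @param seed master seed
#' @return data.frame, one row per woman with a lesion that passed the gate:
#'   `id`, `onset_age`, `preclinical_entry_age`, `latent_exit_age`,
#'   `latent_exit_type` (`clinical_dcis`/`invasive`/`regressed`), `exit_age`,
#'   `exit_type` (latent type or `censored_by_death`),
#'   `other_cause_death_age`
#' @export
simulate_dcis_cohort <- function(cohort, dp, seed) {
  n <- nrow(cohort)
  u_onset <- stream_runif(n, seed, "dcis", "onset")
  u_gate <- stream_runif(n, seed, "dcis", "gate")
  u_lat <- stream_runif(n, seed, "dcis", "latency")
  u_exit_t <- stream_runif(n, seed, "dcis", "exit_time")
  u_exit_w <- stream_runif(n, seed, "dcis", "exit_which")

  onset <- dp$onset_min_age - log(1 - u_onset) / dp$onset_rate
  progresses <- u_gate < dp$progression_fraction
  keep <- progresses & onset < 120
  if (!any(keep)) return(empty_dcis_frame())

  entry <- onset[keep] - dp$latency_mean_years * log(1 - u_lat[keep])
  lam <- c(dp$rate_to_clinical, dp$rate_to_invasive, dp$rate_regress)
  total <- sum(lam)
  hold <- -log(1 - u_exit_t[keep]) / total
  which_exit <- findInterval(u_exit_w[keep], cumsum(lam / total),
                             left.open = TRUE) + 1L
  types <- c("clinical_dcis", "invasive", "regressed")
  latent_exit_age <- entry + hold
  latent_type <- types[pmin(which_exit, 3L)]

  ocd <- cohort$other_cause_death_age[keep]
  censored <- latent_exit_age > ocd
  data.frame(
    id = cohort$id[keep],
    onset_age = onset[keep],
    preclinical_entry_age = entry,
    latent_exit_age = latent_exit_age,
    latent_exit_type = latent_type,
    exit_age = ifelse(censored, ocd, latent_exit_age),
    exit_type = ifelse(censored, "censored_by_death", latent_type),
    other_cause_death_age = ocd,
    stringsAsFactors = FALSE
  )
}

empty_dcis_frame <- function() {
  data.frame(id = integer(), onset_age = numeric(),
             preclinical_entry_age = numeric(), latent_exit_age = numeric(),
             latent_exit_type = character(), exit_age = numeric(),
             exit_type = character(), other_cause_death_age = numeric(),
             stringsAsFactors = FALSE)
}

#' Screen DCIS histories and estimate sojourn and overdiagnosis
#'
#' Applies a screening schedule (shared ages for all women) to simulated DCIS
#' histories: at each screen age inside a woman's preclinical window
#' (`preclinical_entry_age <= age < exit_age`, while she is alive) the lesion
#' is detected with probability `dcis_sensitivity`, with the per-screen
#' uniform keyed on (woman, age) so denser schedules reuse draws at shared
#' ages. Screen-detected lesions are treated as excised (progression halts).
#'
#' A screen-detected lesion is overdiagnosed when its counterfactual exit is
#' regression, or its counterfactual clinical/invasive date falls after
#' other-cause death — i.e. it would never have been diagnosed in the woman's
#' remaining lifetime.
#'
#' @param histories output of [simulate_dcis_cohort()]
#' @param screen_ages numeric vector of screening ages (may be empty)
#' @param dp a [dcis_parameters()] object
#' @param seed master seed (detection draws only)
#' @return list: `mean_sojourn` (mean observed preclinical sojourn, years,
#'   over non-screen-detected lesions with an uncensored exit),
#'   `n_screen_detected`, `overdiagnosis_fraction` (`NA` with an explanatory
#'   `note` when nothing was screen-detected), `detected` (per-lesion flags)
#' @export
estimate_dcis_metrics <- function(histories, screen_ages, dp, seed = 1L) {
  h <- histories
  m <- nrow(h)
  detected_age <- rep(NA_real_, m)
  if (m && length(screen_ages)) {
    for (a in sort(screen_ages)) {
      u <- stream_runif(max(h$id), seed, "dcis_screen", a)[h$id]
      hit <- is.na(detected_age) & h$preclinical_entry_age <= a &
        a < h$exit_age & a < h$other_cause_death_age &
        u < dp$dcis_sensitivity
      detected_age[hit] <- a
    }
  }
  screen_detected <- !is.na(detected_age)
  overdx <- screen_detected &
    (h$latent_exit_type == "regressed" |
       h$latent_exit_age > h$other_cause_death_age)

  uncensored <- !screen_detected & h$exit_type != "censored_by_death"
  mean_sojourn <- if (any(uncensored)) {
    mean(h$exit_age[uncensored] - h$preclinical_entry_age[uncensored])
  } else NA_real_

  n_det <- sum(screen_detected)
  list(
    mean_sojourn = mean_sojourn,
    n_screen_detected = n_det,
    overdiagnosis_fraction = if (n_det > 0) sum(overdx) / n_det else NA_real_,
    note = if (n_det == 0) "no screen-detected DCIS: fraction undefined" else NULL,
    detected = screen_detected,
    detected_age = detected_age,
    overdiagnosed = overdx
  )
}

#' Sweep DCIS submodels over progression fractions and regression settings
#'
#' @param cohort a [build_cohort()] data.frame
#' @param progression_fractions numeric vector (e.g. `c(0.3, 0.5, 0.8)`)
#' @param regression named numeric: regression rates to pair with each run
#'   (`c(off = 0, on = 0.15)` style)
#' @param screen_ages screening ages applied to every submodel
#' @param seed master seed
#' @param ... further arguments to [dcis_parameters()]
#' @return data.frame, one row per (fraction, regression) submodel with the
#'   estimated mean sojourn and overdiagnosis fraction
#' @export
dcis_sweep <- function(cohort, progression_fractions = c(0.3, 0.5, 0.8),
                       regression = c(off = 0, on = 0.15),
                       screen_ages = seq(50, 74, by = 2), seed = 1L, ...) {
  grid <- expand.grid(progression_fraction = progression_fractions,
                      regression_label = names(regression),
                      stringsAsFactors = FALSE)
  grid$rate_regress <- regression[grid$regression_label]
  out <- grid
  out$mean_sojourn <- NA_real_
  out$n_screen_detected <- NA_integer_
  out$overdiagnosis_fraction <- NA_real_
  for (k in seq_len(nrow(grid))) {
    dp <- dcis_parameters(progression_fraction = grid$progression_fraction[k],
                          rate_regress = grid$rate_regress[k], ...)
    h <- simulate_dcis_cohort(cohort, dp, seed)
    est <- estimate_dcis_metrics(h, screen_ages, dp, seed)
    out$mean_sojourn[k] <- est$mean_sojourn
    out$n_screen_detected[k] <- est$n_screen_detected
    out$overdiagnosis_fraction[k] <- est$overdiagnosis_fraction
  }
  out
}
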