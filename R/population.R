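# Person level: birth cohort, other-cause death, BI-RADS density trajectory,
# and a scalar breast-cancer relative-risk multiplier. Everything here is
# scenario-invariant: it is generated once per cohort and shared by every
# intervention scenario (the common-random-numbers contract).

#' Define a person-level risk profile
#'
#' Collapses person-level risk modifiers (family history, polygenic risk,
#' childhood chest radiation, Down syndrome, ...) into a breast-cancer
#' incidence multiplier plus an other-cause mortality hazard multiplier.
#' For example, a Down-syndrome profile carries roughly 75% lower
#' breast-cancer risk (`risk_multiplier = 0.25`) together with a markedly
#' shorter life expectancy (`other_cause_hazard_multiplier > 1`).
#'
#' @param label short label, e.g. `"average"`, `"family_history"`
#' @param risk_multiplier relative breast-cancer incidence (> 0)
#' @param other_cause_hazard_multiplier relative other-cause mortality (>= 0)
#' @param description free text
#' @return an object of class `mammosim_risk_profile`
#' @export
risk_profile <- function(label = "average", risk_multiplier = 1,
                         other_cause_hazard_multiplier = 1,
                         description = "") {
  if (risk_multiplier <= 0) stop("risk_multiplier must be > 0")
  if (other_cause_hazard_multiplier < 0)
    stop("other_cause_hazard_multiplier must be >= 0")
  structure(list(label = label, risk_multiplier = risk_multiplier,
                 other_cause_hazard_multiplier = other_cause_hazard_multiplier,
                 description = description),
            class = "mammosim_risk_profile")
}

# piecewise-constant hazard per single-year age bin from annual death probs;
# qx = 1 maps to an effectively infinite hazard (death within the bin)
life_table_hazards <- function(life_table, multiplier = 1) {
  lt <- life_table[order(life_table$age), ]
  if (!identical(as.integer(lt$age), 0:119))
    stop("life table must cover ages 0-119 in single years")
  h <- -log1p(-pmin(lt$qx, 1 - 1e-15)) * multiplier
  h[lt$qx >= 1] <- 1e9
  h
}

# inverse-transform a vector of uniforms through a piecewise-constant hazard
# on unit age bins starting at `start_age`; returns Inf where total cumulative
# hazard is never exceeded
pch_inverse <- function(u, hazards, start_age = 0) {
  ch <- c(0, cumsum(hazards))
  target <- -log(1 - u)
  bin <- findInterval(target, ch, left.open = TRUE)  # 1-based bin index
  out <- rep(Inf, length(u))
  inside <- bin <= length(hazards)
  b <- bin[inside]
  out[inside] <- start_age + (b - 1) + (target[inside] - ch[b]) / hazards[b]
  out
}

#' Sample an age at death from other causes
#'
#' Continuous age via a piecewise-constant hazard within single-year life
#' table bins, scaled by the profile's other-cause hazard multiplier, drawn by
#' inverse transform. Ages are capped at 120 (the terminal bin has death
#' probability 1).
#'
#' @param life_table data.frame with columns `age` (0-119) and `qx` (annual
#'   death probability, 1 at the cap)
#' @param profile a [risk_profile()]
#' @param u uniform draw(s) in (0,1); supply a vector for a whole cohort
#' @return continuous death age(s) in (0, 120]
#' @export
sample_other_cause_death <- function(life_table, profile = risk_profile(), u) {
  h <- life_table_hazards(life_table, profile$other_cause_hazard_multiplier)
  pmin(pch_inverse(u, h), 120)
}

#' Solve stay probabilities for the stay-or-step-down density model
#'
#' Density is assigned at age 40 from the observed prevalence; at ages 50 and
#' 65 each woman keeps her category or steps down exactly one (d -> c -> b ->
#' a). Given marginal prevalences at the two ends of a transition this is a
#' triangular system, solved from the highest category down. Categories with
#' no mass at the earlier age get a vacuous stay probability of 1.
#'
#' @param prev_from,prev_to length-4 prevalence vectors over categories
#'   (a, b, c, d), each summing to 1
#' @return named numeric vector of stay probabilities for (a, b, c, d)
#' @export
solve_density_stay <- function(prev_from, prev_to) {
  stopifnot(length(prev_from) == 4, length(prev_to) == 4)
  if (abs(sum(prev_from) - 1) > 1e-9 || abs(sum(prev_to) - 1) > 1e-9)
    stop("prevalences must each sum to 1")
  stay <- rep(1, 4)
  inflow <- 0  # mass arriving from the category above
  for (k in 4:1) {
    if (prev_from[k] > 0) {
      stay[k] <- (prev_to[k] - inflow) / prev_from[k]
      if (stay[k] < -1e-9 || stay[k] > 1 + 1e-9)
        stop("infeasible density marginals at category ",
             DENSITY_CATEGORIES[k], ": stay probability ",
             format(stay[k]), " outside [0,1]")
      stay[k] <- min(max(stay[k], 0), 1)
    } else if (abs(prev_to[k] - inflow) > 1e-9) {
      stop("infeasible density marginals at category ",
           DENSITY_CATEGORIES[k],
           ": target mass cannot be reached (one-step-down rule)")
    }
    inflow <- prev_from[k] * (1 - stay[k])
  }
  stats::setNames(stay, DENSITY_CATEGORIES)
}

#' Solve both density transitions (40 to 50, 50 to 65)
#'
#' @param prevalence data.frame with columns `age` (40, 50, 65), `category`,
#'   `prob` — as in `params$density_prevalence`
#' @return list with `stay_40_50` and `stay_50_65` stay-probability vectors
#' @export
solve_density_transitions <- function(prevalence) {
  pv <- function(a) {
    df <- prevalence[prevalence$age == a, ]
    df$prob[match(DENSITY_CATEGORIES, df$category)]
  }
  list(stay_40_50 = solve_density_stay(pv(40), pv(50)),
       stay_50_65 = solve_density_stay(pv(50), pv(65)))
}

# vectorised trajectory assignment: u0 picks the age-40 category from the
# prevalence, u1/u2 decide stay-vs-step at 50 and 65; constant after 65
assign_density_trajectory <- function(prev40, transitions, u0, u1, u2) {
  c40 <- findInterval(u0, cumsum(prev40), left.open = TRUE) + 1L
  c40 <- pmin(c40, 4L)
  step1 <- u1 >= transitions$stay_40_50[c40]
  c50 <- pmax(c40 - as.integer(step1), 1L)
  step2 <- u2 >= transitions$stay_50_65[c50]
  c65 <- pmax(c50 - as.integer(step2), 1L)
  data.frame(density_40 = DENSITY_CATEGORIES[c40],
             density_50 = DENSITY_CATEGORIES[c50],
             density_65 = DENSITY_CATEGORIES[c65])
}

#' Build a birth cohort of women
#'
#' Samples, for `n` women of one birth year and risk profile: an other-cause
#' death age from the cohort life table, and a BI-RADS density trajectory at
#' ages 40/50/65 satisfying the never-increasing (stay-or-step-down-one)
#' rule. Density is assigned at age 40 for every woman regardless of survival
#' or screening, for bookkeeping. All draws come from substreams keyed on
#' `(seed, purpose)`, so the cohort is identical across scenarios and
#' reproducible byte-for-byte.
#'
#' @param n cohort size (>= 1)
#' @param birth_year calendar year of birth
#' @param profile a [risk_profile()]
#' @param params a `mammosim_params` object
#' @param seed master seed
#' @return data.frame, one row per woman: `id`, `birth_year`,
#'   `other_cause_death_age`, `density_40/50/65`, `risk_multiplier`,
#'   `risk_profile_label`
#' @export
build_cohort <- function(n, birth_year, profile = risk_profile(),
                         params, seed) {
  if (n < 1) stop("n must be >= 1")
  u_death <- stream_runif(n, seed, "cohort", "oc_death")
  death_age <- sample_other_cause_death(params$life_table, profile, u_death)

  trans <- solve_density_transitions(params$density_prevalence)
  dp <- params$density_prevalence
  prev40 <- dp$prob[dp$age == 40][match(DENSITY_CATEGORIES,
                                        dp$category[dp$age == 40])]
  dens <- assign_density_trajectory(
    prev40, trans,
    stream_runif(n, seed, "cohort", "density40"),
    stream_runif(n, seed, "cohort", "density50"),
    stream_runif(n, seed, "cohort", "density65"))

  data.frame(
    id = seq_len(n),
    birth_year = birth_year,
    other_cause_death_age = death_age,
    dens,
    risk_multiplier = profile$risk_multiplier,
    risk_profile_label = profile$label,
    stringsAsFactors = FALSE
  )
}
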