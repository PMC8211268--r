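# Shared fixtures and oracles, all built in code.

default_params <- function(variant = "hazard_reduction", seed = 1L) {
  make_default_parameters(variant, seed)
}

# params with a flat clinical-incidence hazard (per 100,000) at every age
flat_incidence_params <- function(rate, seed = 1L) {
  p <- make_default_parameters("hazard_reduction", seed)
  p$incidence_table <- data.frame(age_lo = 0, age_hi = Inf,
                                  year_lo = 1900, year_hi = Inf,
                                  rate = rate)
  p
}

# constant-annual-hazard life table (plus mandatory terminal 1)
constant_hazard_life_table <- function(h) {
  qx <- rep(1 - exp(-h), 120)
  qx[120] <- 1
  data.frame(age = 0:119, qx = qx)
}

# a synthetic cohort frame without sampling (for unit-level tests)
fixed_cohort <- function(death_ages, birth_year = 1960) {
  n <- length(death_ages)
  data.frame(id = seq_len(n), birth_year = birth_year,
             other_cause_death_age = death_ages,
             density_40 = "b", density_50 = "b", density_65 = "b",
             risk_multiplier = 1, risk_profile_label = "average",
             stringsAsFactors = FALSE)
}

# brute-force day-grid oracle: discrete-time simulation of a life table
# (independent of the package's inverse-transform path)
day_grid_death_sample <- function(life_table, n, mult = 1, days = 365L) {
  h_year <- -log(1 - pmin(life_table$qx[order(life_table$age)], 1 - 1e-15)) *
    mult
  h_year[life_table$qx >= 1] <- 1e9
  p_day <- 1 - exp(-rep(h_year, each = days) / days)
  surv <- cumprod(1 - p_day)
  cdf <- 1 - surv
  u <- runif(n)
  day <- findInterval(u, cdf) + 1
  pmin(day / days, 120)
}

# Monte-Carlo standard error of a proportion
mc_se <- function(p, n) sqrt(p * (1 - p) / n)

biennial_50_74 <- function() {
  screening_strategy("biennial 50-74",
                     data.frame(start_age = 50, end_age = 74, interval = 2))
}

annual_50_74 <- function() {
  screening_strategy("annual 50-74",
                     data.frame(start_age = 50, end_age = 74, interval = 1))
}
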