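# Parameter tables: synthetic defaults, validation, CSV/JSON round-trip.
# All rates are per 100,000 woman-years; probabilities are decimals.

#' Tumor molecular subtypes (ER by HER2 status)
#' @export
SUBTYPES <- c("ER+/HER2-", "ER+/HER2+", "ER-/HER2+", "ER-/HER2-")

#' Invasive stages (SEER historical-stage proxy)
#' @export
STAGES <- c("local", "regional", "distant")

#' BI-RADS density categories, a (fatty) to d (extremely dense)
#' @export
DENSITY_CATEGORIES <- c("a", "b", "c", "d")

#' Treatment modalities
#' @export
MODALITIES <- c("chemotherapy", "endocrine", "trastuzumab")

# age-group stratifications, one per parameter family (half-open [lo, hi))
.AGE_GROUPS <- list(
  subtype  = list(breaks = c(0, 50, Inf), labels = c("<50", "50+")),
  stage    = list(breaks = c(0, 50, 65, Inf), labels = c("<50", "50-64", "65+")),
  perf     = list(breaks = c(0, 40, 50, 65, Inf),
                  labels = c("25-39", "40-49", "50-64", "65+")),
  diss     = list(breaks = c(0, 50, 70, Inf), labels = c("<50", "50-69", "70+")),
  survival = list(breaks = c(0, 50, 65, Inf), labels = c("<50", "50-64", "65+")),
  decade   = list(breaks = c(0, 40, 50, 60, 70, Inf),
                  labels = c("<40", "40-49", "50-59", "60-69", "70+")),
  std      = list(breaks = c(0, 50, 70, Inf), labels = c("0-49", "50-69", "70+"))
)

#' Map ages to a named age-group stratification
#'
#' @param age numeric vector of ages in years
#' @param family one of `"subtype"`, `"stage"`, `"perf"`, `"diss"`,
#'   `"survival"`, `"decade"`, `"std"` — each parameter family carries its own
#'   group boundaries; intervals are half-open `[lo, hi)` with the top group
#'   unbounded.
#' @return character vector of group labels
#' @export
age_group_of <- function(age, family) {
  g <- .AGE_GROUPS[[family]]
  if (is.null(g)) stop("unknown age-group family: ", family)
  g$labels[findInterval(age, g$breaks)]  # left-closed bins, top unbounded
}

interval_class_of <- function(gap_years) {
  # map the actual gap since the previous attended screen to a Table-1-style
  # interval class; first screens are handled by the `first` column instead
  ifelse(gap_years < 1.5, "annual",
         ifelse(gap_years < 2.5, "biennial", "triennial"))
}

#' Generate the default synthetic parameter set
#'
#' Produces a fully populated, internally consistent parameter set whose
#' stratification shapes follow the standard input families of multilevel
#' breast-cancer microsimulation models: other-cause life table, background
#' clinical incidence (tabular or the linear-trend variant anchored at 167 per
#' 100,000 in 1975 with a 0.5 per 100,000 annual increment), ER/HER2 subtype
#' proportions by age group, sojourn means by subtype and age decade, BI-RADS
#' density prevalence at ages 40/50/65, mammography performance by age group,
#' density, interval class and first-vs-subsequent screen, stage distributions
#' by detection mode, stage dwell means, baseline breast-cancer survival
#' hazards, treatment dissemination, and treatment efficacy.
#'
#' The *values* are plausible but explicitly uncalibrated synthetic defaults;
#' only the strata shapes are taken from the published input taxonomy. Screen
#' detection is constructed to be stage-shifted earlier than clinical
#' detection, and baseline survival hazards are ordered local < regional <
#' distant.
#'
#' @param variant `"hazard_reduction"` (treatment multiplies the
#'   breast-cancer death hazard by per-modality hazard ratios) or
#'   `"cure_fraction"` (treatment cures with per-modality probabilities;
#'   hazard ratios are set to 1).
#' @param seed integer; jitters the synthetic tables reproducibly so distinct
#'   seeds give distinct (still valid) parameter sets.
#' @return an object of class `mammosim_params`
#' @examples
#' p <- make_default_parameters("hazard_reduction", seed = 1)
#' background_rate(p, age = 60, year = 1990)
#' @export
make_default_parameters <- function(variant = c("hazard_reduction", "cure_fraction"),
                                    seed = 1L) {
  variant <- match.arg(variant)
  # strip expand.grid attributes and element names so tables compare equal
  # after a CSV round trip
  clean <- function(df) {
    attr(df, "out.attrs") <- NULL
    rownames(df) <- NULL
    df[] <- lapply(df, unname)
    df
  }
  jit <- function(x, amt, key) {
    u <- stream_runif(length(x), seed, "params", key)
    round(x * (1 + amt * (2 * u - 1)), 4)
  }

  # other-cause mortality: Gompertz-Makeham-ish annual death probabilities
  age <- 0:119
  qx <- 0.0004 + 2.5e-5 * exp(0.092 * age)
  qx <- pmin(qx, 1)
  qx[length(qx)] <- 1
  life_table <- data.frame(age = age, qx = round(qx, 6))

  # background clinical incidence per 100,000 by age band (calendar-constant
  # table default); the linear 1975 variant is carried alongside
  inc_lo <- c(0, 30, 40, 50, 60, 70, 80)
  inc_hi <- c(30, 40, 50, 60, 70, 80, Inf)
  inc_rate <- c(5, 60, 150, 250, 330, 390, 410)
  incidence_table <- data.frame(
    age_lo = inc_lo, age_hi = inc_hi,
    year_lo = 1900, year_hi = Inf,
    rate = jit(inc_rate, 0.05, "incidence")
  )

  subtype_probs <- data.frame(
    age_group = rep(.AGE_GROUPS$subtype$labels, each = 4),
    subtype = rep(SUBTYPES, 2),
    prob = c(0.55, 0.15, 0.08, 0.22,   # <50: more HER2+/triple-negative
             0.70, 0.10, 0.05, 0.15)   # 50+: ER+ dominates
  )

  # preclinical sojourn means (years): longer for ER+ and older ages
  dec <- .AGE_GROUPS$decade$labels
  base_sojourn <- c(1.5, 2.0, 2.5, 3.0, 3.5)
  subtype_mult <- c(`ER+/HER2-` = 1.3, `ER+/HER2+` = 1.0,
                    `ER-/HER2+` = 0.8, `ER-/HER2-` = 0.7)
  sojourn_means <- expand.grid(subtype = SUBTYPES, age_decade = dec,
                               stringsAsFactors = FALSE)
  sojourn_means$mean_years <- round(
    base_sojourn[match(sojourn_means$age_decade, dec)] *
      subtype_mult[sojourn_means$subtype], 4)

  # BI-RADS prevalence: density declines with age (mass moves a-ward)
  density_prevalence <- data.frame(
    age = rep(c(40L, 50L, 65L), each = 4),
    category = rep(DENSITY_CATEGORIES, 3),
    prob = c(0.06, 0.38, 0.44, 0.12,
             0.10, 0.42, 0.40, 0.08,
             0.16, 0.46, 0.33, 0.05)
  )

  perf <- expand.grid(
    age_group = .AGE_GROUPS$perf$labels,
    density = DENSITY_CATEGORIES,
    interval_class = c("annual", "biennial", "triennial"),
    first = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  sens_age <- c(`25-39` = 0.70, `40-49` = 0.77, `50-64` = 0.83, `65+` = 0.87)
  sens_den <- c(a = 0.07, b = 0.03, c = -0.03, d = -0.12)
  sens_int <- c(annual = -0.03, biennial = 0.00, triennial = 0.03)
  perf$sensitivity <- pmin(0.99, pmax(0.3,
    sens_age[perf$age_group] + sens_den[perf$density] +
      sens_int[perf$interval_class] + ifelse(perf$first, 0.02, 0)))
  spec_age <- c(`25-39` = 0.86, `40-49` = 0.89, `50-64` = 0.91, `65+` = 0.93)
  perf$specificity <- pmin(0.995, pmax(0.5,
    spec_age[perf$age_group] + 0.4 * sens_den[perf$density] -
      ifelse(perf$first, 0.04, 0)))
  perf$sensitivity <- round(perf$sensitivity, 4)
  perf$specificity <- round(perf$specificity, 4)

  # screen-detected tumors are stage-shifted earlier than clinical
  sg <- .AGE_GROUPS$stage$labels
  stage_dists <- rbind(
    data.frame(mode = "screen", age_group = rep(sg, each = 3),
               stage = rep(STAGES, 3),
               prob = rep(c(0.76, 0.20, 0.04), 3)),
    data.frame(mode = "clinical", age_group = rep(sg, each = 3),
               stage = rep(STAGES, 3),
               prob = rep(c(0.55, 0.35, 0.10), 3))
  )

  dwell_means <- data.frame(stage = c("local", "regional"),
                            mean_years = c(2.5, 1.5))

  growth_params <- list(d0_mm = 2, dmax_mm = 128, rate = 0.5, lag_years = 0.5,
                        screen_threshold_mm = 5, clinical_threshold_mm = 20)

  surv <- expand.grid(age_group = .AGE_GROUPS$survival$labels,
                      stage = STAGES, subtype = SUBTYPES,
                      stringsAsFactors = FALSE)
  stage_haz <- c(local = 0.01, regional = 0.05, distant = 0.25)
  subtype_haz <- c(`ER+/HER2-` = 0.8, `ER+/HER2+` = 1.0,
                   `ER-/HER2+` = 1.3, `ER-/HER2-` = 1.6)
  age_haz <- c(`<50` = 1.0, `50-64` = 1.0, `65+` = 1.15)
  surv$hazard <- round(stage_haz[surv$stage] * subtype_haz[surv$subtype] *
                         age_haz[surv$age_group], 5)

  diss <- expand.grid(
    age_group = .AGE_GROUPS$diss$labels, stage = STAGES, subtype = SUBTYPES,
    period = c("1975-1999", "2000+"), modality = MODALITIES,
    stringsAsFactors = FALSE
  )
  base_p <- c(chemotherapy = 0.55, endocrine = 0.75, trastuzumab = 0.6)
  stage_p <- c(local = 0.8, regional = 1.1, distant = 1.2)
  period_p <- c(`1975-1999` = 0.7, `2000+` = 1.0)
  age_p <- c(`<50` = 1.1, `50-69` = 1.0, `70+` = 0.75)
  diss$prob <- round(pmin(0.98, base_p[diss$modality] * stage_p[diss$stage] *
                            period_p[diss$period] * age_p[diss$age_group]), 4)

  if (variant == "hazard_reduction") {
    efficacy <- data.frame(modality = MODALITIES,
                           hazard_ratio = c(0.70, 0.70, 0.65),
                           cure_probability = c(0, 0, 0))
  } else {
    efficacy <- data.frame(modality = MODALITIES,
                           hazard_ratio = c(1, 1, 1),
                           cure_probability = c(0.25, 0.25, 0.30))
  }

  standard_population <- data.frame(
    age_group = .AGE_GROUPS$std$labels,
    weight = c(0.62, 0.26, 0.12)
  )

  p <- structure(list(
    life_table = clean(life_table),
    incidence_mode = "table",
    incidence_table = clean(incidence_table),
    linear_params = list(baseline = 167, increment = 0.5),
    age_profile = NULL,
    subtype_probs = clean(subtype_probs),
    sojourn_means = clean(sojourn_means),
    density_prevalence = clean(density_prevalence),
    performance = clean(perf),
    stage_dists = clean(stage_dists),
    dwell_means = clean(dwell_means),
    growth_params = growth_params,
    survival_baseline = clean(surv),
    dissemination = clean(diss),
    efficacy = clean(efficacy),
    efficacy_mechanism = variant,
    biopsy_prob = 0.5,
    standard_population = clean(standard_population)
  ), class = "mammosim_params")
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks every invariant the simulator relies on: probabilities in `[0, 1]`,
#' categorical distributions summing to 1 within 1e-9, non-negative hazards,
#' strictly positive sojourn means, age-group labels matching the expected
#' strata. Violations are collected and reported together, each naming the
#' offending table and stratum.
#'
#' @param p a `mammosim_params` object (or plain list with the same fields)
#' @return `p`, invisibly, if valid; otherwise an error listing every problem
#' @export
validate_parameters <- function(p) {
  errs <- character()
  add <- function(...) errs[[length(errs) + 1L]] <<- paste0(...)

  need <- c("life_table", "incidence_mode", "linear_params", "subtype_probs",
            "sojourn_means", "density_prevalence", "performance",
            "stage_dists", "survival_baseline", "dissemination", "efficacy",
            "efficacy_mechanism", "biopsy_prob", "standard_population")
  for (f in need) if (is.null(p[[f]])) add("missing table: ", f)
  if (length(errs)) stop(paste(errs, collapse = "\n"))

  lt <- p$life_table
  if (!setequal(lt$age, 0:119)) add("life_table: must cover ages 0-119")
  if (any(lt$qx < 0 | lt$qx > 1)) add("life_table: qx outside [0,1]")
  if (abs(lt$qx[lt$age == 119] - 1) > 1e-12)
    add("life_table: terminal probability at age 119 must be 1")

  check_dist <- function(df, by, table) {
    key <- interaction(df[by], drop = TRUE, sep = ", ")
    s <- tapply(df$prob, key, sum)
    bad <- which(abs(s - 1) > 1e-9)
    for (i in bad)
      add(table, ": distribution for stratum [", names(s)[i], "] sums to ",
          format(s[i]), ", not 1")
    if (any(df$prob < 0 | df$prob > 1))
      add(table, ": probability outside [0,1]")
  }
  check_dist(p$subtype_probs, "age_group", "subtype_probs")
  check_dist(p$density_prevalence, "age", "density_prevalence")
  check_dist(p$stage_dists, c("mode", "age_group"), "stage_dists")
  if (abs(sum(p$standard_population$weight) - 1) > 1e-9)
    add("standard_population: weights sum to ",
        format(sum(p$standard_population$weight)), ", not 1")

  if (any(p$sojourn_means$mean_years <= 0)) {
    bad <- p$sojourn_means[p$sojourn_means$mean_years <= 0, ]
    add("sojourn_means: non-positive mean for stratum [",
        paste(bad$subtype[1], bad$age_decade[1], sep = ", "), "]")
  }
  if (!is.null(p$dwell_means) && any(p$dwell_means$mean_years <= 0))
    add("dwell_means: non-positive mean")

  pf <- p$performance
  if (any(pf$sensitivity < 0 | pf$sensitivity > 1 |
          pf$specificity < 0 | pf$specificity > 1))
    add("performance: sensitivity/specificity outside [0,1]")

  if (any(p$survival_baseline$hazard < 0))
    add("survival_baseline: negative hazard")
  if (any(p$dissemination$prob < 0 | p$dissemination$prob > 1))
    add("dissemination: probability outside [0,1]")
  ef <- p$efficacy
  if (any(ef$hazard_ratio <= 0 | ef$hazard_ratio > 1))
    add("efficacy: hazard_ratio outside (0,1]")
  if (any(ef$cure_probability < 0 | ef$cure_probability >= 1))
    add("efficacy: cure_probability outside [0,1)")
  if (!p$efficacy_mechanism %in% c("hazard_reduction", "cure_fraction"))
    add("efficacy_mechanism: must be hazard_reduction or cure_fraction")
  if (p$biopsy_prob < 0 || p$biopsy_prob > 1)
    add("biopsy_prob: outside [0,1]")
  if (p$incidence_mode == "table") {
    if (is.null(p$incidence_table)) add("missing table: incidence_table")
    else if (any(p$incidence_table$rate < 0))
      add("incidence_table: negative rate")
  }
  lp <- p$linear_params
  if (lp$baseline < 0 || lp$increment < 0)
    add("linear_params: negative rate")

  if (length(errs)) stop(paste(errs, collapse = "\n"))
  invisible(p)
}

#' Background clinical-incidence rate
#'
#' In `table` mode, returns the tabulated rate for the (age, calendar-year)
#' cell. In `linear_1975` mode, returns `baseline + increment * (year - 1975)`
#' — the linear no-screening trend anchored at roughly 167 per 100,000 in 1975
#' with an annual increment of 0.5 per 100,000 (0.3% of baseline) — optionally
#' multiplied by an age-profile table when one is supplied.
#'
#' @param params a `mammosim_params` object
#' @param age age in years
#' @param year calendar year (must be >= 1975 in linear mode)
#' @return rate per 100,000 woman-years (vectorised over `age`/`year`)
#' @export
background_rate <- function(params, age, year) {
  n <- max(length(age), length(year))
  age <- rep_len(age, n); year <- rep_len(year, n)
  if (params$incidence_mode == "linear_1975") {
    if (any(year < 1975))
      stop("background_rate: year before 1975 in linear_1975 mode")
    lp <- params$linear_params
    r <- lp$baseline + lp$increment * (year - 1975)
    if (!is.null(params$age_profile)) {
      ap <- params$age_profile
      i <- findInterval(age, ap$age_lo)
      if (any(i == 0 | age >= ap$age_hi[pmax(i, 1)]))
        stop("background_rate: age outside age_profile table range")
      r <- r * ap$multiplier[i]
    }
    r
  } else {
    tab <- params$incidence_table
    out <- numeric(n)
    for (k in seq_len(n)) {
      hit <- which(tab$age_lo <= age[k] & age[k] < tab$age_hi &
                     tab$year_lo <= year[k] & year[k] < tab$year_hi)
      if (!length(hit))
        stop("background_rate: age ", age[k], " / year ", year[k],
             " outside incidence table range")
      out[k] <- tab$rate[hit[1]]
    }
    out
  }
}

# -- persistence ---------------------------------------------------------

.PARAM_TABLES <- c("life_table", "incidence_table", "subtype_probs",
                   "sojourn_means", "density_prevalence", "performance",
                   "stage_dists", "dwell_means", "survival_baseline",
                   "dissemination", "efficacy", "standard_population",
                   "age_profile")

# write a data.frame as CSV with exact (17 significant digit) doubles
write_table_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.finite(out[[j]]),
                         sprintf("%.17g", out[[j]]),
                         as.character(out[[j]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
}

#' Write a parameter set to a directory
#'
#' Writes one CSV per parameter table plus a `config.json` master file holding
#' the scalar fields and the table file names. The pair round-trips exactly
#' through [load_parameters()].
#'
#' @param p a `mammosim_params` object
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_parameters <- function(p, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list()
  for (nm in .PARAM_TABLES) {
    if (is.null(p[[nm]])) next
    fn <- paste0(nm, ".csv")
    write_table_exact(p[[nm]], file.path(dir, fn))
    tables[[nm]] <- fn
  }
  cfg <- list(
    format = "mammosim-params-1",
    note = paste("Synthetic, uncalibrated default parameter tables;",
                 "strata shapes follow the standard multilevel model inputs,",
                 "values are illustrative only."),
    incidence_mode = p$incidence_mode,
    linear_params = p$linear_params,
    growth_params = p$growth_params,
    efficacy_mechanism = p$efficacy_mechanism,
    biopsy_prob = p$biopsy_prob,
    tables = tables
  )
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load and validate a parameter set
#'
#' @param path a directory written by [write_parameters()], or the
#'   `config.json` file inside one
#' @return a validated `mammosim_params` object
#' @export
load_parameters <- function(path) {
  cfg_path <- if (dir.exists(path)) file.path(path, "config.json") else path
  if (!file.exists(cfg_path)) stop("config file not found: ", cfg_path)
  cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  dir <- dirname(cfg_path)
  p <- list(
    incidence_mode = cfg$incidence_mode,
    linear_params = as.list(cfg$linear_params),
    growth_params = if (!is.null(cfg$growth_params)) as.list(cfg$growth_params),
    efficacy_mechanism = cfg$efficacy_mechanism,
    biopsy_prob = cfg$biopsy_prob,
    age_profile = NULL
  )
  for (nm in names(cfg$tables)) {
    fp <- file.path(dir, cfg$tables[[nm]])
    if (!file.exists(fp)) stop("missing table: ", nm, " (", fp, ")")
    p[[nm]] <- utils::read.csv(fp, stringsAsFactors = FALSE)
  }
  class(p) <- "mammosim_params"
  validate_parameters(p)
  p
}

#' @export
print.mammosim_params <- function(x, ...) {
  cat("<mammosim_params>\n")
  cat("  incidence_mode:", x$incidence_mode,
      sprintf("(linear: %.1f + %.2f/yr from 1975)",
              x$linear_params$baseline, x$linear_params$increment), "\n")
  cat("  efficacy_mechanism:", x$efficacy_mechanism, "\n")
  for (nm in .PARAM_TABLES) {
    if (!is.null(x[[nm]]))
      cat(sprintf("  %-20s %d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

# -- stratum lookups used by downstream modules --------------------------

subtype_prob_vector <- function(params, age) {
  g <- age_group_of(age, "subtype")
  df <- params$subtype_probs[params$subtype_probs$age_group == g, ]
  if (!nrow(df)) stop("subtype_probs: undefined age group ", g)
  stats::setNames(df$prob[match(SUBTYPES, df$subtype)], SUBTYPES)
}

sojourn_mean_of <- function(params, subtype, age) {
  d <- age_group_of(age, "decade")
  df <- params$sojourn_means
  m <- df$mean_years[df$subtype == subtype & df$age_decade == d]
  if (!length(m)) stop("sojourn_means: undefined stratum [", subtype, ", ", d, "]")
  m
}

stage_dist_of <- function(params, mode, age) {
  g <- age_group_of(age, "stage")
  df <- params$stage_dists[params$stage_dists$mode == mode &
                             params$stage_dists$age_group == g, ]
  if (!nrow(df)) stop("stage_dists: undefined stratum [", mode, ", ", g, "]")
  stats::setNames(df$prob[match(STAGES, df$stage)], STAGES)
}

performance_of <- function(params, age, density, interval_class, first) {
  g <- age_group_of(age, "perf")
  pf <- params$performance
  i <- which(pf$age_group == g & pf$density == density &
               pf$interval_class == interval_class & pf$first == first)
  if (!length(i))
    stop("performance: undefined stratum [", g, ", ", density, ", ",
         interval_class, ", first=", first, "]")
  c(sensitivity = pf$sensitivity[i[1]], specificity = pf$specificity[i[1]])
}

dissemination_prob_of <- function(params, age, stage, subtype, year, modality) {
  g <- age_group_of(age, "diss")
  d <- params$dissemination
  per <- sort(unique(d$period))
  # periods encoded "YYYY-YYYY" or "YYYY+": pick the one covering `year`
  lo <- as.numeric(sub("[-+].*$|\\+$", "", per))
  hi <- ifelse(grepl("\\+$", per), Inf,
               suppressWarnings(as.numeric(sub("^\\d+-", "", per))) + 1)
  year <- max(year, min(lo))  # earliest period covers all prior years
  k <- which(lo <= year & year < hi)
  if (!length(k)) stop("dissemination: no period covers year ", year)
  i <- which(d$age_group == g & d$stage == stage & d$subtype == subtype &
               d$period == per[k[1]] & d$modality == modality)
  if (!length(i))
    stop("dissemination: undefined stratum [", g, ", ", stage, ", ", subtype,
         ", ", per[k[1]], ", ", modality, "]")
  d$prob[i[1]]
}

survival_hazard_of <- function(params, age, stage, subtype) {
  g <- age_group_of(age, "survival")
  s <- params$survival_baseline
  i <- which(s$age_group == g & s$stage == stage & s$subtype == subtype)
  if (!length(i))
    stop("survival_baseline: undefined stratum [", g, ", ", stage, ", ",
         subtype, "]")
  s$hazard[i[1]]
}
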