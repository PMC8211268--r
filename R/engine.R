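# Scenario orchestration under common random numbers: one cohort and one set
# of natural histories feed every scenario; scenario-specific draws live in
# their own keyed substreams, so adding a scenario never perturbs another.

#' Run one intervention scenario against fixed natural histories
#'
#' @param cohort a [build_cohort()] data.frame
#' @param nh a [simulate_natural_history()] data.frame from the same seed
#' @param strategy a [screening_strategy()] (use [no_screening()] for none)
#' @param params a `mammosim_params` object
#' @param seed master seed (same as cohort/nh)
#' @param treatment_on assign adjuvant treatment on diagnosis?
#' @param label scenario label
#' @param record_events keep the per-screen event log (slower)
#' @return an object of class `mammosim_result`: per-1,000-women counters
#'   (`screens`, `false_positives`, `benign_biopsies`, `interval_cancers`,
#'   `screen_detected`, `clinically_detected`, `overdiagnosed`,
#'   `bc_deaths`), the per-woman `log`, and the screen `events` (if kept)
#' @export
run_scenario <- function(cohort, nh, strategy, params, seed,
                         treatment_on = TRUE, label = strategy$label,
                         record_events = FALSE) {
  n <- nrow(cohort)
  stopifnot(nrow(nh) == n)
  mech <- attr(nh, "stage_mechanism")
  if (is.null(mech)) mech <- "table"

  mode <- character(n); det_age <- rep(NA_real_, n)
  stage <- rep(NA_character_, n); lead <- rep(NA_real_, n)
  death_age <- numeric(n); cause <- character(n)
  overdx <- logical(n); cured <- logical(n)
  n_scr <- integer(n); n_fp <- integer(n); n_bio <- integer(n)
  intervalc <- logical(n)
  events <- if (record_events) vector("list", n) else NULL
  base_ages <- strategy_base_ages(strategy)
  crow <- lapply(seq_len(n), function(i) lapply(cohort, .subset2, i))
  trow <- lapply(seq_len(n), function(i) lapply(nh, .subset2, i))

  for (i in seq_len(n)) {
    w <- crow[[i]]
    t <- trow[[i]]
    sc <- screen_woman(w, t, strategy, params, seed,
                       stage_mechanism = mech,
                       record_events = record_events,
                       base_ages = base_ages)
    det <- sc$detection
    tr <- treat_and_resolve(w, t, det, params, treatment_on = treatment_on)
    mode[i] <- det$mode; det_age[i] <- det$age
    stage[i] <- if (is.null(det$stage)) NA_character_ else det$stage
    lead[i] <- det$lead_time
    death_age[i] <- tr$death_age; cause[i] <- tr$cause
    cured[i] <- tr$cured
    overdx[i] <- classify_overdiagnosis(det$mode, t$clinical_detection_age,
                                        w$other_cause_death_age)
    n_scr[i] <- sc$n_screens; n_fp[i] <- sc$n_false_positives
    n_bio[i] <- sc$n_benign_biopsies; intervalc[i] <- sc$interval_cancer
    if (record_events) events[[i]] <- sc$events
  }

  log <- data.frame(
    id = cohort$id, birth_year = cohort$birth_year,
    other_cause_death_age = cohort$other_cause_death_age,
    mode = mode, detection_age = det_age, stage = stage, lead_time = lead,
    overdiagnosed = overdx, cured = cured,
    death_age = death_age, cause = cause,
    n_screens = n_scr, n_false_positives = n_fp,
    n_benign_biopsies = n_bio, interval_cancer = intervalc,
    stringsAsFactors = FALSE
  )
  per1000 <- function(x) sum(x) / n * 1000
  structure(list(
    label = label, n = n, seed = seed, treatment_on = treatment_on,
    counters = c(
      screens = per1000(n_scr),
      false_positives = per1000(n_fp),
      benign_biopsies = per1000(n_bio),
      interval_cancers = per1000(intervalc),
      screen_detected = per1000(mode == "screen"),
      clinically_detected = per1000(mode == "clinical"),
      overdiagnosed = per1000(overdx),
      bc_deaths = per1000(cause == "breast_cancer")
    ),
    log = log,
    events = if (record_events) do.call(rbind, events) else NULL
  ), class = "mammosim_result")
}

#' @export
print.mammosim_result <- function(x, ...) {
  cat("<mammosim_result>", x$label, "-", x$n, "women, seed", x$seed, "\n")
  cat("  per 1,000 women:\n")
  for (nm in names(x$counters))
    cat(sprintf("    %-20s %8.2f\n", nm, x$counters[[nm]]))
  invisible(x)
}

#' Run a full multi-scenario configuration
#'
#' Builds the cohort and natural histories once (keyed on the master seed),
#' then runs every scenario against them. Per-woman natural-history columns
#' are therefore identical across scenarios — the common-random-number
#' contract — and each scenario's extra randomness (screen outcomes,
#' attendance) lives in substreams keyed on purpose and screen age.
#'
#' @param config list with fields `n`, `birth_year`, `seed`, optional
#'   `variant` (`"hazard_reduction"`/`"cure_fraction"`), optional
#'   `risk_profile` (arguments for [risk_profile()]), optional
#'   `sojourn_mode`, `stage_mechanism`, optional `params`
#'   (a ready `mammosim_params` overrides `variant`), and `scenarios`: a
#'   named list, each with `strategy` (a [screening_strategy()] or `NULL`)
#'   and `treatment_on`
#' @param record_events keep per-screen event logs
#' @return list: `results` (named `mammosim_result`s), `summary` (tidy
#'   data.frame of counters), `cohort`, `nh`, `params`, `manifest`
#' @export
run_scenarios <- function(config, record_events = FALSE) {
  seed <- config$seed %||% 1L
  params <- config$params %||%
    make_default_parameters(config$variant %||% "hazard_reduction", seed)
  prof <- do.call(risk_profile, as.list(config$risk_profile %||% list()))
  cohort <- build_cohort(config$n, config$birth_year, prof, params, seed)
  nh <- simulate_natural_history(
    cohort, params, seed,
    sojourn_mode = config$sojourn_mode %||% "exponential",
    stage_mechanism = config$stage_mechanism %||% "table")

  results <- list()
  for (nm in names(config$scenarios)) {
    sc <- config$scenarios[[nm]]
    strat <- sc$strategy %||% no_screening()
    results[[nm]] <- run_scenario(cohort, nh, strat, params, seed,
                                  treatment_on = isTRUE(sc$treatment_on),
                                  label = nm,
                                  record_events = record_events)
  }
  summary <- do.call(rbind, lapply(results, function(r) {
    data.frame(scenario = r$label, output = names(r$counters),
               per_1000 = unname(r$counters), stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("mammosim")),
    seed = seed, n = config$n, birth_year = config$birth_year,
    variant = params$efficacy_mechanism,
    stage_mechanism = config$stage_mechanism %||% "table",
    scenarios = names(config$scenarios),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  list(results = results, summary = summary, cohort = cohort, nh = nh,
       params = params, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The four attribution scenarios (none, screening only, treatment only,
#' both) on one cohort
#'
#' @param config as in [run_scenarios()] but with a single `strategy` field;
#'   the four scenario arms are constructed automatically
#' @param year calendar year for the mortality-rate comparison; defaults to
#'   `birth_year + 85` (near end of follow-up)
#' @param method attribution method (see [attribute_reduction()])
#' @param metric `"cumulative"` (breast-cancer deaths by `year` per 100,000
#'   women; stable in a single cohort) or `"in_year"` (age-adjusted deaths
#'   per 100,000 woman-years within `year`)
#' @return list: the four `mammosim_result`s, the four mortality rates, and
#'   the [attribute_reduction()] output
#' @export
run_attribution <- function(config, year = NULL, method = "shapley",
                            metric = c("cumulative", "in_year")) {
  metric <- match.arg(metric)
  config$scenarios <- list(
    none = list(strategy = NULL, treatment_on = FALSE),
    screen_only = list(strategy = config$strategy, treatment_on = FALSE),
    treat_only = list(strategy = NULL, treatment_on = TRUE),
    both = list(strategy = config$strategy, treatment_on = TRUE)
  )
  run <- run_scenarios(config)
  year <- year %||% (config$birth_year + 85)
  rate <- function(nm) {
    lg <- run$results[[nm]]$log
    if (metric == "in_year") {
      mortality_rate_in_year(lg, year, run$params)
    } else {
      sum(lg$cause == "breast_cancer" &
            lg$birth_year + lg$death_age < year) / nrow(lg) * 1e5
    }
  }
  m <- c(none = rate("none"), screen_only = rate("screen_only"),
         treat_only = rate("treat_only"), both = rate("both"))
  list(results = run$results, rates = m,
       attribution = attribute_reduction(unname(m["none"]),
                                         unname(m["screen_only"]),
                                         unname(m["treat_only"]),
                                         unname(m["both"]),
                                         method = method),
       year = year)
}

#' Write a scenario run to disk (tidy CSV results, JSONL events, manifest)
#'
#' @param run output of [run_scenarios()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$summary, file.path(dir, "results.csv"),
                   row.names = FALSE)
  for (nm in names(run$results)) {
    r <- run$results[[nm]]
    utils::write.csv(r$log, file.path(dir, paste0("log_", nm, ".csv")),
                     row.names = FALSE)
    if (!is.null(r$events)) {
      con <- file(file.path(dir, paste0("events_", nm, ".jsonl")), "w")
      for (i in seq_len(nrow(r$events)))
        writeLines(jsonlite::toJSON(as.list(r$events[i, ]),
                                    auto_unbox = TRUE), con)
      close(con)
    }
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
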