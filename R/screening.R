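# Health-system level: screening strategies, schedules, stratified test
# performance, detections and false positives against fixed natural
# histories. Screen results never alter the natural history except by
# triggering diagnosis.

#' Define a screening strategy
#'
#' A strategy is an ordered list of non-overlapping age segments, each with a
#' screening interval; common published strategies map directly, e.g.
#' biennial 50-74 is one segment, "Annual 45-54, Biennial 55-74" is two, and
#' one-time screening at age 50 is a degenerate segment `(50, 50)`.
#'
#' @param label strategy label
#' @param segments data.frame with columns `start_age`, `end_age`,
#'   `interval` (years; ignored for a degenerate `start == end` segment)
#' @param dissemination `"full_adherence"`, or a list
#'   `list(first_age_dist = data.frame(age, prob), attendance = p)` thinning
#'   the schedule empirically: screens before the woman's drawn first-screen
#'   age are dropped and each remaining screen is attended with probability
#'   `attendance`
#' @return an object of class `mammosim_strategy`
#' @examples
#' biennial_50_74 <- screening_strategy("biennial 50-74",
#'   data.frame(start_age = 50, end_age = 74, interval = 2))
#' @export
screening_strategy <- function(label, segments,
                               dissemination = "full_adherence") {
  stopifnot(all(c("start_age", "end_age", "interval") %in% names(segments)))
  segments <- segments[order(segments$start_age), , drop = FALSE]
  if (any(segments$start_age > segments$end_age))
    stop("segment start must be <= end")
  if (nrow(segments) > 1 &&
      any(segments$start_age[-1] <= segments$end_age[-nrow(segments)]))
    stop("overlapping screening segments")
  structure(list(label = label, segments = segments,
                 dissemination = dissemination),
            class = "mammosim_strategy")
}

#' The empty (no-screening) strategy
#' @export
no_screening <- function() {
  screening_strategy("no screening",
                     data.frame(start_age = numeric(), end_age = numeric(),
                                interval = numeric()))
}

#' Enumerate screen ages for one woman
#'
#' Screens run from each segment's start every `interval` years. Across a
#' segment boundary the next screen is `max(next segment start, previous
#' screen + new interval)`. The schedule is truncated at the segment end and
#' at the woman's other-cause death. Under empirical dissemination the
#' schedule is thinned by an age-at-first-screen draw and per-screen
#' attendance draws, keyed on (woman, age) so schedules stay aligned.
#'
#' @param strategy a [screening_strategy()]
#' @param death_age the woman's other-cause death age
#' @param woman_id woman id (attendance stream key)
#' @param seed master seed (attendance draws only)
#' @param base_ages precomputed [strategy_base_ages()] (engine fast path)
#' @return ordered numeric vector of attended screen ages
#' @export
build_schedule <- function(strategy, death_age = Inf, woman_id = 1L,
                           seed = 1L, base_ages = NULL) {
  ages <- (base_ages %||% strategy_base_ages(strategy))
  ages <- ages[ages < death_age]
  dis <- strategy$dissemination
  if (!identical(dis, "full_adherence") && length(ages)) {
    fa <- dis$first_age_dist
    u0 <- stream_runif(1, seed, "attend_first", woman_id)
    first_age <- fa$age[pmin(findInterval(u0, cumsum(fa$prob),
                                          left.open = TRUE) + 1L, nrow(fa))]
    ages <- ages[ages >= first_age]
    keep <- vapply(ages, function(a)
      stream_runif(1, seed, "attend", woman_id, a) < dis$attendance,
      logical(1))
    ages <- ages[keep]
  }
  ages
}

#' Enumerate a strategy's screen ages before death truncation/thinning
#'
#' @param strategy a [screening_strategy()]
#' @return ordered numeric vector of scheduled ages
#' @export
strategy_base_ages <- function(strategy) {
  segs <- strategy$segments
  ages <- numeric()
  prev <- -Inf
  for (k in seq_len(nrow(segs))) {
    iv <- max(segs$interval[k], 1e-9)
    a <- max(segs$start_age[k], if (is.finite(prev)) prev + iv else -Inf)
    while (a <= segs$end_age[k] + 1e-9) {
      ages <- c(ages, a)
      prev <- a
      a <- a + iv
      if (segs$start_age[k] == segs$end_age[k]) break  # one-time segment
    }
  }
  ages
}

#' Perform one mammogram
#'
#' If the woman's tumor is in its preclinical screen-detectable window
#' (`onset <= age < clinical_detection_age`, half-open: a screen exactly at
#' the clinical age is moot) the result is `true_positive` with the stratum
#' sensitivity, else `false_negative`. Without a tumor in window the result
#' is `false_positive` with (1 - specificity), else `true_negative`; false
#' positives lead to a benign biopsy with `biopsy_prob`.
#'
#' @param params a `mammosim_params` object
#' @param age screen age
#' @param density the woman's BI-RADS category at this age
#' @param in_window is a tumor's preclinical window covering this age?
#' @param first first-ever screen?
#' @param gap_years years since previous attended screen (ignored if first)
#' @param u detection uniform; `u_biopsy` biopsy uniform
#' @param u_biopsy biopsy uniform
#' @return list: `result` (one of `true_positive`, `false_negative`,
#'   `false_positive`, `true_negative`), `led_to_biopsy`
#' @export
perform_screen <- function(params, age, density, in_window, first,
                           gap_years = NA, u, u_biopsy = 1) {
  cls <- if (first) "annual" else interval_class_of(gap_years)
  pf <- performance_of(params, age, density, cls, first)
  if (in_window) {
    res <- if (u < pf["sensitivity"]) "true_positive" else "false_negative"
  } else {
    res <- if (u < 1 - pf["specificity"]) "false_positive" else "true_negative"
  }
  list(result = res,
       led_to_biopsy = res == "false_positive" && u_biopsy < params$biopsy_prob)
}

density_at_age <- function(woman, age) {
  if (age < 50) woman$density_40
  else if (age < 65) woman$density_50
  else woman$density_65  # constant after 65
}

#' Run screening for one woman against her fixed natural history
#'
#' Walks the schedule, applying [perform_screen()] at each attended age with
#' detection uniforms keyed on (woman, age) — nested schedules therefore
#' reuse draws at shared ages, the common-random-number property that makes
#' paired strategy contrasts exact. Stops at the first true positive or at
#' the latent clinical-detection age, whichever comes first.
#'
#' @param woman one row of a [build_cohort()] data.frame
#' @param tumor the woman's row of [simulate_natural_history()] (or `NULL`)
#' @param strategy a [screening_strategy()]
#' @param params a `mammosim_params` object
#' @param seed master seed
#' @return list: `detection` (`mode` = `"screen"`/`"clinical"`/`"none"`,
#'   `age`, `stage`, `lead_time`), `events` data.frame of screen events, and
#'   counters `n_screens`, `n_false_positives`, `n_benign_biopsies`,
#'   `interval_cancer` (clinical surfacing after >= 1 false-negative screen)
#' @export
screen_woman <- function(woman, tumor, strategy, params, seed,
                         stage_mechanism = "table", record_events = TRUE,
                         base_ages = NULL) {
  has_tumor <- !is.null(tumor) && isTRUE(tumor$has_tumor)
  onset <- if (has_tumor) tumor$preclinical_onset_age else Inf
  clin <- if (has_tumor) tumor$clinical_detection_age else Inf
  death <- woman$other_cause_death_age
  schedule <- build_schedule(strategy, death, woman$id, seed, base_ages)
  # screening stops mattering once the tumor has surfaced clinically
  schedule <- schedule[schedule < min(clin, death)]

  events <- list()
  prev_age <- NA_real_
  n_screens <- 0L; n_fp <- 0L; n_biopsy <- 0L
  had_false_negative <- FALSE
  det_mode <- "none"; det_age <- NA_real_
  for (k in seq_along(schedule)) {
    a <- schedule[k]
    in_window <- has_tumor && onset <= a && a < clin
    u <- stream_runif(1, seed, "screen_test", woman$id, a)
    # u_biopsy is lazily evaluated inside perform_screen: the biopsy
    # substream is only consulted on a false positive
    ev <- perform_screen(params, a, density_at_age(woman, a), in_window,
                         first = k == 1L, gap_years = a - prev_age, u = u,
                         u_biopsy = stream_runif(1, seed, "screen_biopsy",
                                                 woman$id, a))
    n_screens <- n_screens + 1L
    if (record_events) {
      events[[k]] <- data.frame(woman_id = woman$id, age = a,
                                result = ev$result, first_screen = k == 1L,
                                led_to_biopsy = ev$led_to_biopsy,
                                stringsAsFactors = FALSE)
    }
    prev_age <- a
    if (ev$result == "false_positive") {
      n_fp <- n_fp + 1L
      if (ev$led_to_biopsy) n_biopsy <- n_biopsy + 1L
    }
    if (ev$result == "false_negative") had_false_negative <- TRUE
    if (ev$result == "true_positive") {
      det_mode <- "screen"; det_age <- a
      break
    }
  }

  if (det_mode == "none" && has_tumor && clin < death) {
    det_mode <- "clinical"; det_age <- clin
  }
  stage <- if (det_mode == "none") NA_character_ else
    detection_stage(tumor, det_mode, det_age, params, stage_mechanism)
  list(
    detection = list(mode = det_mode, age = det_age, stage = stage,
                     lead_time = if (det_mode == "screen") clin - det_age
                                 else NA_real_),
    events = if (length(events)) do.call(rbind, events) else NULL,
    n_screens = n_screens,
    n_false_positives = n_fp,
    n_benign_biopsies = n_biopsy,
    interval_cancer = det_mode == "clinical" && had_false_negative
  )
}

# stage at detection under the active mechanism; table mode reuses the
# woman's stage uniform for both modes so the quantiles stay coupled
detection_stage <- function(tumor, mode, age, params, mech = "table") {
  if (mech == "dwell" && !is.na(tumor$entry_regional)) {
    ent <- c(local = tumor$preclinical_onset_age,
             regional = tumor$entry_regional, distant = tumor$entry_distant)
    stage_at(ent, age)
  } else if (mech == "growth") {
    gp <- params$growth_params
    t_since <- gompertz_crossing_time(gp$screen_threshold_mm, gp) +
      (age - tumor$preclinical_onset_age)
    stage_from_diameter(gompertz_diameter(t_since, gp))
  } else {
    assign_stage(params, mode, age, tumor$u_stage)
  }
}
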