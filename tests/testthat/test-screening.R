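test_that("schedules enumerate the stated conventions", {
  expect_equal(build_schedule(biennial_50_74(), death_age = 90),
               seq(50, 74, by = 2))
  expect_length(build_schedule(biennial_50_74(), death_age = 90), 13)

  acs <- screening_strategy("annual 45-54, biennial 55-74",
                            data.frame(start_age = c(45, 55),
                                       end_age = c(54, 74),
                                       interval = c(1, 2)))
  sched <- build_schedule(acs, death_age = 90)
  expect_equal(sched, c(45:54, seq(56, 74, by = 2)))
  expect_length(sched, 20)

  one <- screening_strategy("one-time 50",
                            data.frame(start_age = 50, end_age = 50,
                                       interval = 1))
  expect_equal(build_schedule(one, death_age = 90), 50)
  expect_length(build_schedule(one, death_age = 49), 0)

  expect_error(screening_strategy("bad",
    data.frame(start_age = c(50, 60), end_age = c(65, 74),
               interval = c(1, 2))), "overlap")
})

test_that("empirical dissemination thins but never reorders the schedule", {
  strat <- screening_strategy("biennial empirical",
    data.frame(start_age = 50, end_age = 74, interval = 2),
    dissemination = list(
      first_age_dist = data.frame(age = c(50, 54, 58), prob = c(0.5, 0.3, 0.2)),
      attendance = 0.8))
  full <- seq(50, 74, by = 2)
  for (w in 1:25) {
    s <- build_schedule(strat, death_age = 90, woman_id = w, seed = 31)
    expect_true(all(s %in% full))
    expect_true(!is.unsorted(s))
  }
  # attendance fraction over many women approximates 0.8 of eligible screens
  tot <- vapply(1:400, function(w)
    length(build_schedule(strat, death_age = 90, woman_id = w, seed = 31)),
    numeric(1))
  first <- vapply(1:400, function(w) {
    s <- build_schedule(strat, death_age = 90, woman_id = w, seed = 31)
    if (length(s)) s[1] else NA_real_
  }, numeric(1))
  expect_true(mean(tot) < 13 * 0.95)
})

test_that("perform_screen honors perfect and stochastic performance", {
  p <- default_params()
  p$performance$sensitivity <- 1
  p$performance$specificity <- 1
  ev <- perform_screen(p, 55, "b", in_window = TRUE, first = TRUE, u = 0.99)
  expect_equal(ev$result, "true_positive")
  ev2 <- perform_screen(p, 55, "b", in_window = FALSE, first = FALSE,
                        gap_years = 2, u = 0.001)
  expect_equal(ev2$result, "true_negative")

  p$performance$sensitivity <- 0.8
  set.seed(51)
  hits <- vapply(runif(1e4), function(u)
    perform_screen(p, 55, "b", TRUE, FALSE, 2, u)$result == "true_positive",
    logical(1))
  expect_lt(abs(mean(hits) - 0.8), 3 * mc_se(0.8, 1e4))

  expect_error(perform_screen(p, 55, "z", TRUE, TRUE, u = 0.5), "stratum")
})

test_that("expected false positives equal the sum of (1 - specificity) strata", {
  p <- default_params()
  # 3-screen toy case, no tumor: hand computation over the exact strata
  w <- as.list(fixed_cohort(90)[1, ])
  strat <- screening_strategy("three", data.frame(start_age = 50,
                                                  end_age = 54, interval = 2))
  strata <- list(c("50-64", "b", "annual", TRUE),
                 c("50-64", "b", "biennial", FALSE),
                 c("50-64", "b", "biennial", FALSE))
  pf <- p$performance
  expected <- sum(vapply(strata, function(s) {
    i <- pf$age_group == s[1] & pf$density == s[2] &
      pf$interval_class == s[3] & pf$first == as.logical(s[4])
    1 - pf$specificity[i][1]
  }, numeric(1)))
  fps <- vapply(1:4000, function(k) {
    ww <- w; ww$id <- k
    screen_woman(ww, NULL, strat, p, seed = 53,
                 record_events = FALSE)$n_false_positives
  }, numeric(1))
  expect_lt(abs(mean(fps) - expected), 3 * sqrt(expected) / sqrt(4000))
})

test_that("detection: lead time bounds, window edges, null equivalence", {
  p <- default_params()
  cohort <- build_cohort(1500, 1955, risk_profile(), p, 57)
  nh <- simulate_natural_history(cohort, p, 57)
  res <- run_scenario(cohort, nh, annual_50_74(), p, 57)
  sd <- res$log[res$log$mode == "screen", ]
  expect_gt(nrow(sd), 0)
  expect_true(all(sd$lead_time > 0))
  tum <- nh[match(sd$id, nh$id), ]
  expect_true(all(sd$lead_time <= tum$sojourn_years + 1e-9))

  # sensitivity 0 everywhere is per-woman identical to no screening,
  # except that screens (and their false positives) still happen
  p0 <- p
  p0$performance$sensitivity <- 0
  r0 <- run_scenario(cohort, nh, annual_50_74(), p0, 57)
  rn <- run_scenario(cohort, nh, no_screening(), p0, 57)
  expect_identical(r0$log$mode, rn$log$mode)
  expect_identical(r0$log$death_age, rn$log$death_age)
  expect_identical(r0$log$cause, rn$log$cause)
  expect_equal(unname(r0$counters["screen_detected"]), 0)
})

test_that("nested schedules dominate: screens, FPs, detections weakly larger", {
  p <- default_params()
  cohort <- build_cohort(2500, 1955, risk_profile(), p, 61)
  nh <- simulate_natural_history(cohort, p, 61)
  ra <- run_scenario(cohort, nh, annual_50_74(), p, 61)
  rb <- run_scenario(cohort, nh, biennial_50_74(), p, 61)
  for (cnt in c("screens", "false_positives", "screen_detected",
                "overdiagnosed")) {
    expect_gte(ra$counters[[cnt]], rb$counters[[cnt]])
  }
  # per-woman false positives dominate too (shared draws at shared ages),
  # restricted to women with no tumor (no detection-stopping interplay)
  no_tumor <- !nh$has_tumor
  expect_true(all(ra$log$n_false_positives[no_tumor] >=
                    rb$log$n_false_positives[no_tumor]))
})

test_that("no-screening scenario produces no screening artifacts", {
  p <- default_params()
  cohort <- build_cohort(800, 1950, risk_profile(), p, 67)
  nh <- simulate_natural_history(cohort, p, 67)
  r <- run_scenario(cohort, nh, no_screening(), p, 67)
  expect_equal(unname(r$counters[c("screens", "false_positives",
                                   "benign_biopsies", "screen_detected",
                                   "overdiagnosed")]),
               rep(0, 5))
})
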