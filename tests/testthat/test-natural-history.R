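test_that("clinical incidence follows the cumulative-hazard closed forms", {
  p <- flat_incidence_params(200)
  set.seed(41)
  u <- runif(1e5)
  a <- sample_clinical_incidence(p, 1960, 1, u)
  p80 <- 1 - exp(-0.16)
  expect_lt(abs(mean(!is.na(a) & a < 80) - p80), 3 * mc_se(p80, 1e5))

  a4 <- sample_clinical_incidence(p, 1960, 0.25, u)
  p80q <- 1 - exp(-0.04)
  expect_lt(abs(mean(!is.na(a4) & a4 < 80) - p80q), 3 * mc_se(p80q, 1e5))

  # zero hazard: no tumors, ever
  p0 <- flat_incidence_params(0)
  expect_true(all(is.na(sample_clinical_incidence(p0, 1960, 1, runif(100)))))
})

test_that("latent incidence matches a fine-grid discrete-time oracle (KS < 0.01)", {
  p <- default_params()
  set.seed(42)
  a <- sample_clinical_incidence(p, 1960, 1, runif(1e5))
  a <- a[!is.na(a)]
  # day-grid oracle over the same age-varying hazards
  h <- mammosim:::incidence_hazards(p, 1960, 1)
  p_day <- 1 - exp(-rep(h, each = 365) / 365)
  cdf <- 1 - cumprod(1 - p_day)
  u <- runif(1e5)
  day <- findInterval(u, cdf) + 1
  b <- (day / 365)[day <= length(p_day)]
  ks <- suppressWarnings(ks.test(a, b)$statistic)
  expect_lt(unname(ks), 0.01)
})

test_that("subtype assignment is an age-group multinomial", {
  p <- default_params()
  p$subtype_probs$prob <- rep(c(1, 0, 0, 0), 2)
  expect_true(all(vapply(runif(50), function(u)
    assign_subtype(p, 45, u), character(1)) == "ER+/HER2-"))

  p$subtype_probs$prob <- rep(c(0.6, 0.1, 0.1, 0.2), 2)
  set.seed(43)
  draws <- assign_subtype(p, 60, runif(1e5))
  freq <- as.numeric(table(factor(draws, levels = SUBTYPES))) / 1e5
  for (k in 1:4) {
    pk <- c(0.6, 0.1, 0.1, 0.2)[k]
    expect_lt(abs(freq[k] - pk), 3 * mc_se(pk, 1e5))
  }
})

test_that("sojourn sampling: exponential tail, fixed mode, onset arithmetic", {
  p <- default_params()
  p$sojourn_means$mean_years <- 2
  expect_equal(sample_sojourn(p, "ER+/HER2-", 50, 0.37, mode = "fixed"), 2)

  set.seed(44)
  s <- sample_sojourn(p, "ER+/HER2-", 50, runif(1e5))
  tail4 <- exp(-2)
  expect_lt(abs(mean(s > 4) - tail4), 3 * mc_se(tail4, 1e5))

  # clinical detection at 50 with sojourn 3 -> onset 47
  cohort <- fixed_cohort(90)
  nh <- simulate_natural_history(cohort, p, 1, sojourn_mode = "fixed")
  if (nh$has_tumor[1]) {
    expect_equal(nh$preclinical_onset_age[1],
                 nh$clinical_detection_age[1] - nh$sojourn_years[1])
  }
  p$sojourn_means$mean_years <- -1
  expect_error(sample_sojourn(p, "ER+/HER2-", 50, 0.5), "> 0")
})

test_that("stage tables: degenerate, multinomial, and screen-vs-clinical shift", {
  p <- default_params()
  expect_equal(assign_stage(p, "screen", 55, 0.999), "distant")
  p2 <- p
  p2$stage_dists$prob[p2$stage_dists$mode == "screen"] <- rep(c(1, 0, 0), 3)
  expect_true(all(vapply(runif(20), function(u)
    assign_stage(p2, "screen", 55, u), character(1)) == "local"))

  set.seed(45)
  draws <- vapply(runif(2e4), function(u) assign_stage(p, "clinical", 55, u),
                  character(1))
  frq <- as.numeric(table(factor(draws, levels = STAGES))) / 2e4
  expected <- c(0.55, 0.35, 0.10)
  for (k in 1:3) expect_lt(abs(frq[k] - expected[k]),
                           3 * mc_se(expected[k], 2e4))

  # fixture constraint: screen-detected stages are earlier
  ps <- p$stage_dists
  expect_gt(ps$prob[ps$mode == "screen" & ps$stage == "local"][1],
            ps$prob[ps$mode == "clinical" & ps$stage == "local"][1])
})

test_that("dwell-time progression is exponential with increasing entries", {
  dm <- data.frame(stage = c("local", "regional"), mean_years = c(2, 1.5))
  set.seed(46)
  still_local <- replicate(1e4, {
    e <- progress_stage_dwell(50, dm, runif(2))
    stage_at(e, 51) == "local"
  })
  p1 <- exp(-0.5)
  expect_lt(abs(mean(still_local) - p1), 3 * mc_se(p1, 1e4))

  e <- progress_stage_dwell(50, dm, c(0.5, 0.5))
  expect_true(all(diff(e) > 0))
  expect_error(stage_at(e, 49), "before")

  # effectively infinite dwell: never leaves local
  dinf <- data.frame(stage = c("local", "regional"), mean_years = c(1e12, 1e12))
  einf <- progress_stage_dwell(50, dinf, c(0.5, 0.5))
  expect_equal(stage_at(einf, 119), "local")
})

test_that("Gompertz growth: boundary, asymptote, closed-form crossing vs bisection", {
  gp <- list(d0_mm = 2, dmax_mm = 128, rate = 0.5, lag_years = 1)
  expect_equal(gompertz_diameter(gp$lag_years, gp), 2)
  expect_equal(gompertz_diameter(0.3, gp), 2)  # flat through the lag
  expect_lt(abs(gompertz_diameter(80, gp) - 128), 1e-6)

  t20 <- gompertz_crossing_time(20, gp)
  expect_equal(t20 - gp$lag_years, 2 * log(log(64) / log(6.4)),
               tolerance = 1e-12)
  # independent bisection oracle
  root <- uniroot(function(t) gompertz_diameter(t, gp) - 20,
                  c(gp$lag_years, 100), tol = 1e-10)$root
  expect_equal(t20, root, tolerance = 1e-7)

  d <- gompertz_diameter(seq(0, 30, by = 0.1), gp)
  expect_true(all(diff(d) >= 0))
  expect_error(gompertz_crossing_time(1, gp), "between")
})

test_that("natural histories are scenario-independent and internally consistent", {
  p <- default_params()
  cohort <- build_cohort(300, 1960, risk_profile(), p, 7)
  nh <- simulate_natural_history(cohort, p, 7)
  expect_identical(nh, simulate_natural_history(cohort, p, 7))
  tum <- nh[nh$has_tumor, ]
  expect_true(all(tum$preclinical_onset_age < tum$clinical_detection_age))
  expect_true(all(tum$sojourn_years > 0))
  expect_true(all(tum$subtype %in% SUBTYPES))

  nhd <- simulate_natural_history(cohort, p, 7, stage_mechanism = "dwell")
  tumd <- nhd[nhd$has_tumor, ]
  expect_true(all(tumd$preclinical_onset_age < tumd$entry_regional))
  expect_true(all(tumd$entry_regional < tumd$entry_distant))
})
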