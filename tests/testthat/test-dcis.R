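test_that("DCIS parameter contracts hold", {
  expect_error(dcis_parameters(progression_fraction = 0), "\\(0, 1\\]")
  expect_error(dcis_parameters(rate_to_clinical = 0, rate_to_invasive = 0,
                               rate_regress = 0), "absorbing")
  expect_error(dcis_parameters(rate_to_invasive = -1), ">= 0")
})

test_that("progression gate and regression prohibition are absolute", {
  p <- default_params()
  cohort <- build_cohort(2000, 1960, risk_profile(), p, 9)
  # gate closed: progression_fraction ~ 0 (0 is rejected by the constructor)
  dp <- dcis_parameters(progression_fraction = 1e-12, onset_rate = 0.1)
  h <- simulate_dcis_cohort(cohort, dp, 9)
  expect_equal(nrow(h), 0)

  dp2 <- dcis_parameters(rate_regress = 0, onset_rate = 0.1)
  h2 <- simulate_dcis_cohort(cohort, dp2, 9)
  expect_gt(nrow(h2), 0)
  expect_false(any(h2$exit_type == "regressed"))
})

test_that("competing exits match rate ratios and the mean-sojourn closed form", {
  # deaths far in the future: no censoring
  cohort <- fixed_cohort(rep(1e6, 1e5))
  dp <- dcis_parameters(progression_fraction = 1, rate_to_clinical = 0.1,
                        rate_to_invasive = 0.3, rate_regress = 0.1,
                        onset_rate = 5, onset_min_age = 0)
  h <- simulate_dcis_cohort(cohort, dp, 13)
  expect_gt(nrow(h), 9e4)
  p_reg <- 0.1 / 0.5
  expect_lt(abs(mean(h$latent_exit_type == "regressed") - p_reg),
            3 * mc_se(p_reg, nrow(h)))
  soj <- h$latent_exit_age - h$preclinical_entry_age
  expect_lt(abs(mean(soj) - 2), 3 * 2 / sqrt(nrow(h)))  # exp mean=sd=2

  # chi-square on all three exit types at alpha = 0.001
  obs <- table(factor(h$latent_exit_type,
                      levels = c("clinical_dcis", "invasive", "regressed")))
  expect_gt(chisq.test(obs, p = c(0.2, 0.6, 0.2))$p.value, 0.001)
})

test_that("sojourn estimator recovers the input mean without screening", {
  cohort <- fixed_cohort(rep(1e6, 1e5))
  dp <- dcis_parameters(progression_fraction = 1, rate_to_clinical = 0.25,
                        rate_to_invasive = 0.25, rate_regress = 0,
                        onset_rate = 5, onset_min_age = 0)
  h <- simulate_dcis_cohort(cohort, dp, 17)
  est <- estimate_dcis_metrics(h, numeric(), dp, 17)
  expect_lt(abs(est$mean_sojourn - 2), 3 * 2 / sqrt(nrow(h)))
  expect_true(is.na(est$overdiagnosis_fraction))
  expect_match(est$note, "undefined")
})

test_that("overdiagnosis endpoints: all-surface and regression-only worlds", {
  cohort <- fixed_cohort(rep(1e6, 5000))
  # no regression, death far beyond every exit: nothing is overdiagnosed
  dp0 <- dcis_parameters(progression_fraction = 1, rate_to_clinical = 0.3,
                         rate_to_invasive = 0.3, rate_regress = 0,
                         onset_rate = 0.05, onset_min_age = 25)
  h0 <- simulate_dcis_cohort(cohort, dp0, 19)
  est0 <- estimate_dcis_metrics(h0, seq(30, 90, by = 2), dp0, 19)
  expect_gt(est0$n_screen_detected, 0)
  expect_equal(est0$overdiagnosis_fraction, 0)

  # regression-only: every screen-detected lesion is overdiagnosed
  dp1 <- dcis_parameters(progression_fraction = 1, rate_to_clinical = 0,
                         rate_to_invasive = 0, rate_regress = 0.3,
                         onset_rate = 0.05, onset_min_age = 25)
  h1 <- simulate_dcis_cohort(cohort, dp1, 19)
  est1 <- estimate_dcis_metrics(h1, seq(30, 90, by = 2), dp1, 19)
  expect_gt(est1$n_screen_detected, 0)
  expect_equal(est1$overdiagnosis_fraction, 1)
})

test_that("allowing regression raises DCIS overdiagnosis (paired seeds)", {
  p <- default_params()
  cohort <- build_cohort(3e4, 1950, risk_profile(), p, 23)
  ages <- seq(50, 74, by = 2)
  run <- function(rr) {
    dp <- dcis_parameters(progression_fraction = 0.5, rate_to_clinical = 0.2,
                          rate_to_invasive = 0.3, rate_regress = rr,
                          onset_rate = 0.01, onset_min_age = 25)
    est <- estimate_dcis_metrics(simulate_dcis_cohort(cohort, dp, 23),
                                 ages, dp, 23)
    est$overdiagnosis_fraction
  }
  expect_gte(run(0.25), run(0))
})

test_that("dcis_sweep covers the submodel grid", {
  p <- default_params()
  cohort <- build_cohort(5000, 1950, risk_profile(), p, 29)
  sw <- dcis_sweep(cohort, c(0.3, 0.8), c(off = 0, on = 0.15),
                   screen_ages = seq(50, 74, by = 2), seed = 29,
                   onset_rate = 0.02)
  expect_equal(nrow(sw), 4)
  expect_true(all(is.finite(sw$mean_sojourn)))
  expect_true(all(sw$overdiagnosis_fraction >= 0 &
                    sw$overdiagnosis_fraction <= 1, na.rm = TRUE))
})
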