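test_that("runs are reproducible and natural histories shared across scenarios", {
  strat <- biennial_50_74()
  config <- list(n = 400, birth_year = 1960, seed = 11,
                 scenarios = list(
                   none = list(strategy = NULL, treatment_on = FALSE),
                   screen_only = list(strategy = strat, treatment_on = FALSE),
                   treat_only = list(strategy = NULL, treatment_on = TRUE),
                   both = list(strategy = strat, treatment_on = TRUE)))
  run1 <- run_scenarios(config)
  run2 <- run_scenarios(config)
  expect_identical(run1$summary, run2$summary)
  expect_identical(run1$results$both$log, run2$results$both$log)

  # CRN: person/tumor-level columns identical across the four scenarios
  for (nm in c("screen_only", "treat_only", "both")) {
    expect_identical(run1$results[[nm]]$log$other_cause_death_age,
                     run1$results$none$log$other_cause_death_age)
  }
  expect_identical(run1$nh, simulate_natural_history(run1$cohort,
                                                     run1$params, 11))

  # stream isolation: adding a scenario changes nothing upstream
  config2 <- config
  config2$scenarios$extra <- list(strategy = annual_50_74(),
                                  treatment_on = TRUE)
  run3 <- run_scenarios(config2)
  expect_identical(run3$results$both$log, run1$results$both$log)
})

test_that("write_run produces results, logs, and a manifest", {
  dir <- withr::local_tempdir()
  config <- list(n = 120, birth_year = 1960, seed = 13,
                 scenarios = list(both = list(strategy = biennial_50_74(),
                                              treatment_on = TRUE)))
  run <- run_scenarios(config, record_events = TRUE)
  write_run(run, dir)
  expect_true(file.exists(file.path(dir, "results.csv")))
  expect_true(file.exists(file.path(dir, "log_both.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 13)
  ev <- file.path(dir, "events_both.jsonl")
  expect_true(file.exists(ev))
  first <- jsonlite::fromJSON(readLines(ev, n = 1))
  expect_true(all(c("woman_id", "age", "result") %in% names(first)))
})

test_that("run_attribution wires four arms into shares summing to 100", {
  at <- run_attribution(list(n = 1500, birth_year = 1955, seed = 17,
                             strategy = biennial_50_74()))
  expect_equal(at$attribution$screening_share_pct +
                 at$attribution$treatment_share_pct, 100)
  expect_gt(at$attribution$total_reduction_pct, 0)
  expect_true(all(at$rates[c("screen_only", "treat_only", "both")] <
                    at$rates["none"]))
})

test_that("the CLI covers init/validate/run/attribute with exit-code contracts", {
  dir <- withr::local_tempdir()
  pdir <- file.path(dir, "params")
  expect_equal(mammosim_cli(c("params", "init", "--variant",
                              "hazard_reduction", "--out", pdir)), 0L)
  expect_true(file.exists(file.path(pdir, "config.json")))
  expect_equal(suppressMessages(
    mammosim_cli(c("params", "validate", pdir))), 0L)

  # corrupt a distribution: validate must fail with exit 2
  sp <- file.path(pdir, "subtype_probs.csv")
  tab <- read.csv(sp)
  tab$prob <- 0.5
  write.csv(tab, sp, row.names = FALSE)
  expect_equal(suppressMessages(
    mammosim_cli(c("params", "validate", pdir))), 2L)

  cfg <- list(n = 80, birth_year = 1960, seed = 19,
              scenarios = list(
                both = list(treatment_on = TRUE,
                            strategy = list(label = "biennial",
                                            segments = list(list(
                                              start_age = 50, end_age = 74,
                                              interval = 2))))))
  cfg_path <- file.path(dir, "run.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE)
  out <- file.path(dir, "out")
  expect_equal(suppressMessages(
    mammosim_cli(c("run", "--config", cfg_path, "--out", out))), 0L)
  expect_true(file.exists(file.path(out, "results.csv")))

  # attribution needs a cohort large enough for a positive total reduction
  cfg$n <- 1200
  cfg$strategy <- cfg$scenarios$both$strategy
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE)
  aout <- file.path(dir, "attr")
  expect_equal(suppressMessages(
    mammosim_cli(c("attribute", "--config", cfg_path, "--out", aout))), 0L)
  attr_df <- read.csv(file.path(aout, "attribution.csv"))
  shares <- attr_df$value[attr_df$quantity %in%
                            c("screening_share_pct", "treatment_share_pct")]
  expect_equal(sum(shares), 100)

  expect_equal(suppressMessages(mammosim_cli(c("run"))), 2L)
  expect_equal(suppressMessages(
    mammosim_cli(c("run", "--config", "/nonexistent.json"))), 2L)
  expect_equal(suppressMessages(mammosim_cli("definitely-not-a-command")), 2L)
})
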