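test_that("identical spec and seed give bit-identical counters", {
  spec <- scenario_spec("progressive_only", "annual", n_persons = 3e4,
                        seed = 71)
  a <- run_paired_scenario(spec)
  b <- run_paired_scenario(spec)
  expect_identical(a$sim$unscreened, b$sim$unscreened)
  expect_identical(a$sim$screened, b$sim$screened)
  expect_identical(a$sim$life_years_gained, b$sim$life_years_gained)
})

test_that("the no-screening arm is invariant to the policy (common random numbers)", {
  cfg <- progressive_only()
  none <- simulate_cohort(cfg, n = 3e4, seed = 72)
  annual <- simulate_cohort(cfg, n = 3e4, seed = 72,
                            policy = screening_policy(interval = 1))
  five <- simulate_cohort(cfg, n = 3e4, seed = 72,
                          policy = screening_policy(interval = 5))
  expect_identical(none$unscreened, annual$unscreened)
  expect_identical(annual$unscreened, five$unscreened)
})

test_that("rates are stable across cohort sizes (scale invariance)", {
  cfg <- progressive_only()
  small <- simulate_cohort(cfg, n = 1e5, seed = 73)
  big <- simulate_cohort(cfg, n = 4e5, seed = 74)
  r1 <- rate_per_100k(small$unscreened$pc_deaths,
                      small$unscreened$person_years)
  r2 <- rate_per_100k(big$unscreened$pc_deaths, big$unscreened$person_years)
  # binomial Monte Carlo error at n = 1e5 is ~1.2 per 100k on ~110
  expect_equal(r1, r2, tolerance = 0.05)
})

test_that("scenario specs validate their ranges", {
  expect_error(scenario_spec(pathway = "mystery"))
  expect_error(scenario_spec(specificity = 1.2))
  expect_error(scenario_spec(surgical_mortality = 1))
  spec <- scenario_spec("indolent_included", "five_yearly", n_persons = 10)
  expect_s3_class(spec, "scenario_spec")
})

test_that("uncalibrated configurations produce an instructive error", {
  spec <- scenario_spec("progressive_only", "annual", n_persons = 100)
  raw <- progressive_only(calibrated = FALSE)
  expect_error(run_paired_scenario(spec, config = raw),
               "calibrate_onset_scale")
})

test_that("the sensitivity grid runs and labels every cell", {
  grid <- run_sensitivity_grid("progressive_only", n_persons = 2e4,
                               seed = 75)
  expect_identical(nrow(grid), 11L)
  expect_setequal(unique(grid$variation),
                  c("base", "risk", "sensitivity", "specificity",
                    "treatment_mortality"))
  expect_true(all(is.finite(grid$NNS)))
  # directional checks within the shared-seed grid
  base <- grid[grid$variation == "base", ]
  dbl <- grid[grid$variation == "risk" & grid$value == 2, ]
  hlf <- grid[grid$variation == "risk" & grid$value == 0.5, ]
  expect_lt(dbl$NNS, base$NNS)
  expect_gt(hlf$NNS, base$NNS)
  spec100 <- grid[grid$variation == "specificity" & grid$value == 1, ]
  expect_lt(spec100$NNSurv, base$NNSurv)
})

test_that("reports round-trip through the output directory", {
  dir <- withr::local_tempdir()
  spec <- scenario_spec("progressive_only", "annual", n_persons = 2e4,
                        seed = 76)
  out <- run_paired_scenario(spec)$outcomes
  paths <- write_report(list(out), dir,
                        manifest = list(seed = 76, n_persons = 2e4))
  expect_true(all(file.exists(paths)))
  df <- utils::read.csv(file.path(dir, "base_case_outcomes.csv"))
  expect_equal(df$NNS, out$NNS)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(man$package, "pancscreen")
  expect_identical(man$seed, 76L)
  expect_warning(write_report(list(), withr::local_tempdir()), "manifest only")
})

test_that("pathway presets round-trip through YAML configuration files", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- indolent_included()
  yaml::write_yaml(list(pathway_name = cfg$pathway_name,
                        progressive_stage_means = cfg$progressive_stage_means,
                        indolent_stage_means = cfg$indolent_stage_means,
                        indolent_fraction = cfg$indolent_fraction,
                        onset_rate = cfg$onset_rate,
                        onset_shape = cfg$onset_shape), path)
  cfg2 <- read_pathway_config(path)
  expect_equal(cfg2$indolent_fraction, cfg$indolent_fraction)
  expect_equal(cfg2$onset_rate, cfg$onset_rate)
  expect_equal(cfg2$progressive_stage_means, cfg$progressive_stage_means)
  sim <- simulate_cohort(cfg2, n = 1000, seed = 77)
  expect_equal(sim$unscreened$n, 1000)
})
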