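cfg_prog <- progressive_only()

paired_small <- simulate_cohort(cfg_prog, n = 1e5, seed = 61,
                                policy = screening_policy())

test_that("rates per 100,000 life-years are plain arithmetic", {
  expect_equal(rate_per_100k(921, 697000), 132.1, tolerance = 1e-3)
  expect_equal(rate_per_100k(751, 697000), 107.7, tolerance = 1e-3)
  expect_identical(rate_per_100k(0, 1000), 0)
  expect_error(rate_per_100k(1, 0), "positive")
})

test_that("effectiveness ratios satisfy their defining identities", {
  s <- paired_small$screened
  u <- paired_small$unscreened
  eff <- effectiveness_ratios(s, u)
  expect_equal(eff$NNS * eff$deaths_prevented, s$screen_tests)
  expect_equal(eff$NNSurv * eff$deaths_prevented, s$surveillance_tests)
  expect_equal(eff$NNT * eff$deaths_prevented, s$total_resections)
  # worked Table-2 arithmetic
  eff2 <- effectiveness_ratios(
    list(pc_deaths = 319, screen_tests = 186504,
         surveillance_tests = 20182, total_resections = 1233),
    list(pc_deaths = 751))
  expect_equal(eff2$NNS, 431.7, tolerance = 1e-3)
  expect_equal(eff2$NNSurv, 46.7, tolerance = 1e-3)
  expect_equal(round(eff2$NNT, 1), 2.9)
})

test_that("no deaths prevented yields a flagged undefined ratio, not an error", {
  eff <- effectiveness_ratios(list(pc_deaths = 10, screen_tests = 100,
                                   surveillance_tests = 5,
                                   total_resections = 2),
                              list(pc_deaths = 10))
  expect_true(is.nan(eff$NNS))
  expect_true(attr(eff, "undefined"))
})

test_that("life-years gained sums paired differences and can be negative", {
  null_chars <- test_characteristics(sensitivity = rep(0, 6), specificity = 1)
  sim0 <- simulate_cohort(cfg_prog, n = 1e4, seed = 62,
                          policy = screening_policy(), chars = null_chars)
  expect_identical(life_years_gained(sim0), 0)
  expect_error(life_years_gained(simulate_cohort(cfg_prog, 100, 1)), "paired")
  # lethal surgery makes screening cost life-years
  lethal <- simulate_cohort(cfg_prog, n = 2e4, seed = 63,
                            policy = screening_policy(),
                            mgmt = management_policy(surgical_mortality = 0.99))
  expect_lt(life_years_gained(lethal), 0)
  expect_gt(life_years_gained(paired_small), 0)
})

test_that("paired accounting conserves persons in both arms", {
  for (arm in list(paired_small$unscreened, paired_small$screened)) {
    expect_equal(arm$pc_deaths + arm$other_deaths, arm$n)
  }
  # surgical deaths are inside the PC-related death count
  expect_lte(paired_small$screened$surgical_deaths,
             paired_small$screened$pc_deaths)
})

test_that("count- and rate-based mortality reductions agree closely", {
  o <- outcome_table(paired_small)
  expect_lt(abs(o$death_reduction_pct - o$mortality_reduction_pct), 0.5)
  expect_lte(o$death_reduction_pct, 100)
  expect_gte(o$interval_cancers_total_rate, o$interval_cancers_5y_rate)
})

test_that("interval cancers are clinical diagnoses after a negative screen", {
  sim <- simulate_cohort(cfg_prog, n = 5e4, seed = 64,
                         policy = screening_policy(), person_detail = TRUE)
  p <- sim$persons
  tot <- p$interval_flags %in% c(1, 3)
  expect_equal(sum(tot), sim$screened$interval_cancers_total)
  expect_true(all(!is.na(p$clinical_dx_age[tot])))
  expect_true(all(!is.na(p$last_negative_screen[tot])))
  five <- p$interval_flags == 3
  expect_true(all(p$clinical_dx_age[five] - p$last_negative_screen[five] <= 5))
  # screen-detected cases are never interval cancers
  expect_true(all(p$sd_stage[tot] == 0))
})

test_that("outcome tables flatten to a data frame", {
  df <- outcomes_to_df(outcome_table(paired_small))
  expect_identical(nrow(df), 1L)
  expect_true(all(c("NNS", "NNSurv", "NNT", "lyg") %in% names(df)))
})
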