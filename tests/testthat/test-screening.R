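cfg_prog <- progressive_only()
cfg_ind <- indolent_included()

test_that("screen schedules follow the policy arithmetic", {
  expect_length(screen_schedule(screening_policy(interval = 1)), 26)
  expect_equal(screen_schedule(screening_policy(interval = 5)),
               c(50, 55, 60, 65, 70, 75))
  expect_error(screening_policy(start_age = 80, stop_age = 75))
})

test_that("test application reflects sensitivity and specificity", {
  chars <- test_characteristics()
  set.seed(431)
  u <- runif(4e4)
  expect_equal(mean(apply_test("NONE", chars, u)), 0.10, tolerance = 0.05)
  expect_equal(mean(apply_test("PRECLIN_III_IV", chars, u)), 0.99,
               tolerance = 0.005)
  expect_equal(mean(apply_test("LGD", chars, u)), 0.60, tolerance = 0.02)
  perfect <- test_characteristics(sensitivity = rep(1, 6), specificity = 1)
  expect_true(all(apply_test("HGD", perfect, u)))
  expect_false(any(apply_test("NONE", perfect, u)))
  expect_error(apply_test(7, chars, 0.5))
  # multiplier caps at 1 per stage
  boosted <- test_characteristics(sensitivity_multiplier = 1.10)
  expect_equal(boosted$sensitivity, c(0.66, 0.66, 0.825, 0.99, 1, 1))
})

test_that("management routes positives as configured", {
  mgmt <- management_policy()
  expect_identical(manage_positive("PRECLIN_III_IV", mgmt, 0.001), "palliate")
  expect_identical(manage_positive("PRECLIN_I", mgmt, 0.5), "resect")
  expect_identical(manage_positive("PRECLIN_I", mgmt, 0.95), "surveil")
  none <- management_policy(resect_prob_given_positive = rep(0, 5))
  expect_identical(manage_positive("HGD", none, 0.2), "surveil")
  # false positives are never resected by default
  expect_identical(manage_positive("NONE", mgmt, 0.0001), "surveil")
  ret <- management_policy(return_prob = 0.1)
  expect_identical(manage_positive("LGD", ret, 0.95), "return_to_screening")
})

test_that("sensitivity x resection probability gives the 81% worked example", {
  # one screening round on a preclinical-stage-I cohort
  chars <- test_characteristics()
  mgmt <- management_policy()
  set.seed(432)
  n <- 1e5
  pos <- apply_test("PRECLIN_I", chars, runif(n))
  resected <- pos & vapply(runif(n), function(u)
    manage_positive("PRECLIN_I", mgmt, u) == "resect", logical(1))
  bt <- binom.test(sum(resected), n, p = 0.81)
  expect_gt(bt$p.value, 0.001)
})

test_that("a blind test with perfect specificity reproduces the unscreened arm", {
  null_chars <- test_characteristics(sensitivity = rep(0, 6), specificity = 1)
  sim <- simulate_cohort(cfg_prog, n = 2e4, seed = 33,
                         policy = screening_policy(), chars = null_chars,
                         person_detail = TRUE)
  p <- sim$persons
  expect_identical(p$final_death_screened, p$final_death_unscreened)
  expect_identical(sim$screened$pc_deaths, sim$unscreened$pc_deaths)
  expect_identical(sim$screened$cancer_cases, sim$unscreened$cancer_cases)
  expect_identical(sum(sim$screened$resections), 0)
  expect_identical(sim$screened$surveillance_tests, 0)
  expect_identical(sim$life_years_gained, 0)
})

test_that("compiled engine matches the interpreted reference event-by-event", {
  bad <- compare_engines(cfg_prog, 1:1500, seed = 34)
  expect_identical(bad, integer(0))
  bad <- compare_engines(cfg_ind, 1:1500, seed = 35,
                         policy = screening_policy(interval = 5))
  expect_identical(bad, integer(0))
  # under stressed management parameters too
  bad <- compare_engines(cfg_ind, 1:500, seed = 36,
                         chars = test_characteristics(specificity = 0.7),
                         mgmt = management_policy(
                           resect_prob_given_positive = rep(0.3, 5),
                           return_prob = 0.2,
                           false_positive_surveillance_rounds = 2,
                           surgical_mortality = 0.2))
  expect_identical(bad, integer(0))
})

test_that("screening events stay inside [start_age, death) and follow positives", {
  for (i in seq_len(300)) {
    h <- simulate_screened_history(cfg_ind, lt_default, seed = 37, person = i)
    ages <- h$screen_test_ages
    if (length(ages)) {
      expect_true(all(ages >= 50 & ages <= 75))
      expect_true(all(ages <= h$final_death_age)) # equality: death at surgery
    }
    sv <- h$surveillance_test_ages
    if (length(sv)) {
      expect_gt(length(ages), 0) # surveillance needs a preceding screen
      expect_true(all(sv > min(ages)))
      expect_true(all(sv <= h$final_death_age))
    }
    if (!is.na(h$screen_dx_stage) && h$screen_dx_stage == 6) {
      # palliated stage III/IV keep the fatal survival law
      expect_lte(h$final_death_age, h$screen_dx_age + 5)
    }
  }
})

test_that("persons dead or diagnosed before the start age are never screened", {
  sim <- simulate_cohort(cfg_prog, n = 5e4, seed = 38,
                         policy = screening_policy(), person_detail = TRUE)
  p <- sim$persons
  early <- p$other_cause_death_age < 50 |
    (!is.na(p$dx_age_unscreened) & p$dx_age_unscreened < 50)
  expect_true(all(p$screen_tests[early] == 0))
  expect_true(all(p$final_death_screened[early] ==
                    p$final_death_unscreened[early]))
  # screened exactly when alive and undiagnosed at the screening start age
  eligible <- p$other_cause_death_age > 50 &
    (is.na(p$dx_age_unscreened) | p$dx_age_unscreened > 50)
  expect_identical(sim$screened$ever_screened, as.numeric(sum(eligible)))
  # ~92.5% of persons survive to the screening start age
  expect_equal(mean(p$other_cause_death_age > 50), 0.925, tolerance = 0.01)
})

test_that("surgical mortality extremes behave as specified", {
  lethal <- management_policy(surgical_mortality = 0.99)
  sim <- simulate_cohort(cfg_prog, n = 2e4, seed = 39,
                         policy = screening_policy(), mgmt = lethal,
                         person_detail = TRUE)
  p <- sim$persons
  res <- p$n_resections > 0
  expect_true(all(p$surgical_death[res & p$n_resections == 1] %in% c(0, 1)))
  expect_gt(mean(p$surgical_death[res]), 0.95)
  safe <- management_policy(surgical_mortality = 0)
  sim0 <- simulate_cohort(cfg_prog, n = 2e4, seed = 39,
                          policy = screening_policy(), mgmt = safe)
  expect_identical(sim0$screened$surgical_deaths, 0)
})
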