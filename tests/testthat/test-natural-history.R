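cfg_prog <- progressive_only()
cfg_ind <- indolent_included()

test_that("stage durations hit their means at the exponential mean quantile", {
  v <- 1 - exp(-1) # exponential inverse CDF returns the mean here
  expect_equal(sample_stage_durations(cfg_prog, "progressive", v),
               c(3.33, 3.33, 3.33, 2, 2, 1))
  expect_equal(sample_stage_durations(cfg_ind, "progressive", v),
               c(1.11, 1.11, 1.11, 0.66, 0.66, 0.33))
  di <- sample_stage_durations(cfg_ind, "indolent", v)
  expect_equal(di[1:3], c(7.08, 11.78, 24.15))
  expect_true(all(is.infinite(di[4:6]))) # preclinical I absorbing
})

test_that("dwell-time draws recover the configured means", {
  set.seed(411)
  v <- runif(4e4)
  d <- vapply(v, function(vi)
    sample_stage_durations(cfg_prog, "progressive", vi), numeric(6))
  expect_equal(rowMeans(d), c(3.33, 3.33, 3.33, 2, 2, 1), tolerance = 0.03)
  # one shared quantile: perfect rank correlation between consecutive stages
  expect_equal(cor(d[1, ], d[4, ], method = "spearman"), 1)
})

test_that("mean sojourn from onset to clinical diagnosis matches the closed form", {
  # oracle: expected time to diagnosis with per-stage detection interrupting
  # progression (detection time uniform within the dwell)
  oracle <- function(means, pdx) {
    e3 <- means[6] / 2 # stage III/IV always detected
    e2 <- pdx[2] * means[5] / 2 + (1 - pdx[2]) * (means[5] + e3)
    e1 <- pdx[1] * means[4] / 2 + (1 - pdx[1]) * (means[4] + e2)
    sum(means[1:3]) + e1
  }
  mc_sojourn <- function(cfg, n) {
    set.seed(412)
    mean(vapply(seq_len(n), function(i) {
      d <- sample_stage_durations(cfg, "progressive", runif(1))
      t <- sum(d[1:3])
      for (s in 4:6) {
        det <- sample_clinical_detection(s, d[s], cfg, runif(1))
        if (!is.na(det)) return(t + det)
        t <- t + d[s]
      }
      t
    }, numeric(1)))
  }
  o_prog <- oracle(cfg_prog$progressive_stage_means, cfg_prog$clinical_dx_prob)
  o_ind <- oracle(cfg_ind$progressive_stage_means, cfg_ind$clinical_dx_prob)
  expect_equal(o_prog, 14.125, tolerance = 1e-3) # "estimated mean total preclinical" ~14.3
  expect_equal(o_ind, 4.694, tolerance = 1e-3)   # ~4.8 for the fast pathway
  expect_equal(mc_sojourn(cfg_prog, 2e4), o_prog, tolerance = 0.02)
  expect_equal(mc_sojourn(cfg_ind, 2e4), o_ind, tolerance = 0.02)
})

test_that("clinical detection respects the stage-specific probabilities", {
  set.seed(413)
  u <- runif(4e4)
  det1 <- sample_clinical_detection("PRECLIN_I", 2, cfg_prog, u)
  expect_equal(mean(!is.na(det1)), 0.051, tolerance = 0.1)
  expect_true(all(det1 >= 0 & det1 <= 2, na.rm = TRUE))
  det3 <- sample_clinical_detection("PRECLIN_III_IV", 1, cfg_prog, u)
  expect_true(all(!is.na(det3))) # stage III/IV always surfaces clinically
  cfg0 <- cfg_prog
  cfg0$clinical_dx_prob <- c(0, 0, 1)
  expect_true(all(is.na(sample_clinical_detection(4, 2, cfg0, u))))
  expect_error(sample_clinical_detection("HGD", 2, cfg_prog, 0.5),
               "preclinical")
})

test_that("post-diagnosis survival follows the linear 5-year law", {
  u <- (seq_len(2e4) - 0.5) / 2e4 # deterministic uniform grid
  s1 <- sample_pc_survival("CLINICAL_I", cfg_prog, u)
  expect_equal(mean(is.na(s1)), 0.291, tolerance = 1e-3)   # cured fraction
  # P(death within 2.5y of diagnosis) = (1 - 0.291) / 2
  expect_equal(mean(!is.na(s1) & s1 <= 2.5), 0.3545, tolerance = 1e-3)
  s34 <- sample_pc_survival("CLINICAL_III_IV", cfg_prog, u)
  expect_true(all(!is.na(s34) & s34 > 0 & s34 <= 5)) # always fatal within 5y
  expect_error(sample_pc_survival("LGD", cfg_prog, 0.5))
})

test_that("onset sampling is monotone in the hazard scale and flags misuse", {
  cfg0 <- progressive_only(calibrated = FALSE)
  expect_error(sample_onset_age(cfg0, 0.5), "uncalibrated")
  cfg0$onset_rate <- 0
  expect_true(all(is.na(sample_onset_age(cfg0, runif(10)))))
  # doubling the hazard roughly doubles lifetime risk at low risk
  low <- progressive_only(); low$onset_rate <- 0.05
  dbl <- low; dbl$onset_rate <- 0.10
  m1 <- pancscreen:::measure_unscreened(low, 1e5, 7, lt_default)
  m2 <- pancscreen:::measure_unscreened(dbl, 1e5, 7, lt_default)
  expect_equal(m2$risk / m1$risk, 2, tolerance = 0.08)
  # re-onset conditioning: onset after current_age, stochastically larger
  set.seed(414)
  u <- runif(1000)
  a0 <- sample_onset_age(cfg_prog, u)
  a60 <- sample_onset_age(cfg_prog, u, current_age = 60)
  expect_true(all(a60 > 60, na.rm = TRUE))
  expect_true(all(a60 >= a0 | is.na(a0), na.rm = TRUE))
})

test_that("disease courses satisfy their structural invariants", {
  for (cfg in list(cfg_prog, cfg_ind)) {
    for (i in seq_len(800)) {
      dc <- build_disease_course(cfg, lt_default, seed = 21, person = i)
      expect_identical(dc$final_death_age,
                       min(dc$pc_death_age, dc$other_cause_death_age,
                           na.rm = TRUE))
      if (!is.na(dc$onset_age)) {
        ent <- dc$stage_entry_ages
        fin <- ent[is.finite(ent)]
        expect_true(all(diff(fin) > 0))
        if (!is.na(dc$clinical_dx_age)) {
          expect_gte(dc$clinical_dx_age, ent[dc$clinical_dx_stage])
          if (!is.na(dc$pc_death_age)) {
            expect_gt(dc$pc_death_age, dc$clinical_dx_age)
            expect_lte(dc$pc_death_age, dc$clinical_dx_age + 5)
          }
        }
        # indolent lesions never kill: no diagnosis, no PC death
        if (identical(dc$lesion_fate, "indolent")) {
          expect_true(is.na(dc$clinical_dx_age))
          expect_true(is.na(dc$pc_death_age))
          expect_identical(dc$death_cause, "other")
        }
      } else {
        expect_identical(dc$death_cause, "other")
      }
    }
  }
})

test_that("cohort-level accounting conserves persons and causes", {
  sim <- simulate_cohort(cfg_ind, n = 1e5, seed = 22, person_detail = TRUE)
  u <- sim$unscreened
  expect_equal(u$pc_deaths + u$other_deaths, u$n)
  p <- sim$persons
  # a PC death requires a prior clinical diagnosis
  pc <- p$cause_unscreened == 1
  expect_true(all(!is.na(p$dx_age_unscreened[pc])))
  expect_true(all(p$pc_death_unscreened[pc] > p$dx_age_unscreened[pc]))
  # indolent lesions (fate 2) never produce a PC death
  expect_true(all(p$cause_unscreened[p$fate == 2] == 0))
})
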