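# Shared fixtures (built in code; nothing is read from disk).

# default table is cached inside the package after first use
lt_default <- default_life_table()

# a tiny deterministic table: everyone dies between ages 80 and 81
lt_step80 <- life_table(c(rep(1, 81), rep(0, 30)))

# compare the compiled engine's person rows with the interpreted reference
# engine for the same persons; returns indices of mismatching persons
compare_engines <- function(config, persons, seed,
                            policy = screening_policy(),
                            chars = test_characteristics(),
                            mgmt = management_policy(), tol = 1e-8) {
  n <- max(persons)
  sim <- simulate_cohort(config, n = n, seed = seed, table = lt_default,
                         policy = policy, chars = chars, mgmt = mgmt,
                         person_detail = TRUE)
  p <- sim$persons
  na0 <- function(x, fill = -1) ifelse(is.na(x), fill, x)
  bad <- integer(0)
  for (i in persons) {
    h <- simulate_screened_history(config, lt_default, seed, i,
                                   policy = policy, chars = chars,
                                   mgmt = mgmt)
    ref <- c(length(h$screen_test_ages), length(h$surveillance_test_ages),
             sum(h$resections),
             na0(h$screen_dx_stage, 0), na0(h$screen_dx_age),
             na0(h$clinical_dx_age), na0(h$pc_death_age),
             h$final_death_age, as.numeric(h$surgical_death),
             na0(h$last_negative_screen),
             h$unscreened$final_death_age)
    eng <- c(p$screen_tests[i], p$surveillance_tests[i], p$n_resections[i],
             p$sd_stage[i], na0(p$sd_age[i]),
             na0(p$clinical_dx_age[i]), na0(p$pc_death_screened[i]),
             p$final_death_screened[i], p$surgical_death[i],
             na0(p$last_negative_screen[i]),
             p$final_death_unscreened[i])
    if (!isTRUE(all.equal(ref, eng, tolerance = tol))) bad <- c(bad, i)
  }
  bad
}
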