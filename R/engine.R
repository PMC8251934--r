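# R-level driver for the compiled cohort engine.

#' Simulate a cohort, with or without screening
#'
#' Runs the compiled microsimulation for `n` persons. When a policy is given,
#' both arms (no screening / screening) are produced in a single pass over
#' the cohort with common natural-history random numbers, so the difference
#' between arms isolates the policy effect person by person.
#'
#' @param config a calibrated [pathway_config()].
#' @param n number of simulated persons.
#' @param seed integer seed; together with the person index it fully
#'   determines every draw (identical seed implies bit-identical counters).
#' @param table a [life_table()].
#' @param policy a [screening_policy()], or `NULL` for no screening arm.
#' @param chars a [test_characteristics()].
#' @param mgmt a [management_policy()].
#' @param person_detail if `TRUE`, also return one row per person with both
#'   arms' event summaries (memory: ~22 doubles per person).
#' @return an object of class `cohort_sim`: lists of aggregate counters
#'   `unscreened` and (if a policy was given) `screened`, the summed
#'   `life_years_gained`, and optionally `persons` (a data frame).
#' @examples
#' sim <- simulate_cohort(progressive_only(), n = 1000, seed = 1,
#'                        policy = screening_policy())
#' summary(sim)
#' @export
simulate_cohort <- function(config, n, seed, table = default_life_table(),
                            policy = NULL, chars = test_characteristics(),
                            mgmt = management_policy(),
                            person_detail = FALSE) {
  stopifnot(inherits(config, "pathway_config"), inherits(table, "life_table"))
  screen <- !is.null(policy)
  sc <- if (screen) {
    stopifnot(inherits(policy, "screening_policy"),
              inherits(chars, "test_characteristics"),
              inherits(mgmt, "management_policy"))
    list(schedule = screen_schedule(policy),
         surveillance_interval = policy$surveillance_interval,
         sensitivity = chars$sensitivity,
         specificity = chars$specificity,
         resect_prob = mgmt$resect_prob,
         resect_prob_none = mgmt$resect_prob_none,
         return_prob = mgmt$return_prob,
         surgical_mortality = mgmt$surgical_mortality,
         fp_rounds = mgmt$fp_rounds)
  } else list()
  raw <- cpp_run_cohort(as.integer(n), as.integer(seed), table$survival,
                        unclass(config), screen, sc, person_detail)
  out <- list(unscreened = finish_counters(raw$unscreened),
              screened = if (screen) finish_counters(raw$screened),
              life_years_gained = raw$life_years_gained,
              n = n, seed = seed,
              pathway = config$pathway_name,
              policy = policy)
  if (person_detail) {
    p <- raw$persons
    colnames(p) <- c("other_cause_death_age", "onset_age", "fate",
                     "dx_age_unscreened", "dx_stage_unscreened",
                     "pc_death_unscreened", "final_death_unscreened",
                     "cause_unscreened", "screen_tests",
                     "surveillance_tests", "n_resections",
                     "first_resection_stage", "sd_stage", "sd_age",
                     "surgical_death", "clinical_dx_age", "clinical_dx_stage",
                     "pc_death_screened", "final_death_screened",
                     "cause_screened", "last_negative_screen",
                     "interval_flags")
    out$persons <- as.data.frame(p)
  }
  class(out) <- "cohort_sim"
  out
}

finish_counters <- function(cnt) {
  names(cnt$resections) <- c("LGD", "IGD", "HGD", "PRECLIN_I", "PRECLIN_II",
                             "lesion_free")
  cnt$cancer_cases <- cnt$cases_clinical + cnt$cases_sd_I + cnt$cases_sd_II +
    cnt$cases_sd_III_IV
  cnt$total_resections <- sum(cnt$resections)
  cnt
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("<cohort_sim>", x$pathway, " n =", format(x$n, big.mark = ","),
      " seed =", x$seed, "\n")
  cat(sprintf("  no screening: %d cases, %d PC deaths\n",
              as.integer(x$unscreened$cancer_cases),
              as.integer(x$unscreened$pc_deaths)))
  if (!is.null(x$screened))
    cat(sprintf("  screening:    %d cases, %d PC deaths, %d screen tests\n",
                as.integer(x$screened$cancer_cases),
                as.integer(x$screened$pc_deaths),
                as.integer(x$screened$screen_tests)))
  invisible(x)
}

#' @export
summary.cohort_sim <- function(object, ...) {
  if (is.null(object$screened)) {
    u <- object$unscreened
    cat(sprintf(
      "Unscreened cohort (n = %s): lifetime clinical risk %.2f%%, %0.f PC deaths,\n  mortality %.1f per 100,000 LYs\n",
      format(object$n, big.mark = ","), 100 * u$cases_clinical / u$n,
      u$pc_deaths, rate_per_100k(u$pc_deaths, u$person_years)))
    return(invisible(object))
  }
  print(outcome_table(object))
  invisible(object)
}
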