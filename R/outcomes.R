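# Outcome measures: rates, effectiveness ratios, life-years gained.

#' Events per 100,000 life-years
#'
#' @param count event count.
#' @param person_years life-years at risk.
#' @return `count / person_years * 1e5`.
#' @export
rate_per_100k <- function(count, person_years) {
  if (any(person_years <= 0)) stop("person_years must be positive")
  count / person_years * 1e5
}

#' Effectiveness ratios of a screening scenario
#'
#' Number needed to screen (NNS), to surveil (NNSurv) and to treat (NNT), all
#' per cancer death prevented. Deaths prevented is the between-arm difference
#' in pancreatic-cancer deaths of the paired cohorts (surgical deaths count as
#' PC-related). When screening prevents no deaths the ratios are undefined and
#' returned as `NaN` with attribute `undefined = TRUE` rather than as an
#' error.
#'
#' @param screened,unscreened aggregate counter lists from a paired
#'   [simulate_cohort()] run (fields `pc_deaths`, `screen_tests`,
#'   `surveillance_tests`, `total_resections`).
#' @return named list: `deaths_prevented`, `NNS`, `NNSurv`, `NNT`.
#' @export
effectiveness_ratios <- function(screened, unscreened) {
  prevented <- unscreened$pc_deaths - screened$pc_deaths
  if (prevented <= 0) {
    out <- list(deaths_prevented = prevented, NNS = NaN, NNSurv = NaN,
                NNT = NaN)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  list(deaths_prevented = prevented,
       NNS = screened$screen_tests / prevented,
       NNSurv = screened$surveillance_tests / prevented,
       NNT = screened$total_resections / prevented)
}

#' Life-years gained by screening
#'
#' Sum over paired persons of (screened final death age minus unscreened
#' final death age); negative contributions (e.g. surgical deaths) are
#' included with their sign.
#'
#' @param sim a paired [simulate_cohort()] result.
#' @return years.
#' @export
life_years_gained <- function(sim) {
  stopifnot(inherits(sim, "cohort_sim"))
  if (is.null(sim$screened))
    stop("life_years_gained needs a paired (screened) simulation")
  sim$life_years_gained
}

#' Outcome table for a paired scenario
#'
#' Assembles the standard effectiveness summary of one paired run: disease
#' burden with percent reductions, test and resection counts, life-years
#' gained, interval-cancer rates and NNS/NNSurv/NNT, scaled to a reference
#' cohort size (default: per 10,000 simulated persons).
#'
#' @param sim a paired [simulate_cohort()] result.
#' @param per reference cohort size for scaled counts.
#' @return an object of class `outcome_table` (a list of scalars; see
#'   `print` method).
#' @export
outcome_table <- function(sim, per = 10000) {
  stopifnot(inherits(sim, "cohort_sim"))
  u <- sim$unscreened
  s <- sim$screened
  if (is.null(s)) stop("outcome_table needs a paired (screened) simulation")
  f <- per / sim$n
  inc_u <- rate_per_100k(u$cancer_cases, u$person_years)
  inc_s <- rate_per_100k(s$cancer_cases, s$person_years)
  mort_u <- rate_per_100k(u$pc_deaths, u$person_years)
  mort_s <- rate_per_100k(s$pc_deaths, s$person_years)
  eff <- effectiveness_ratios(s, u)
  out <- list(
    pathway = sim$pathway,
    interval = sim$policy$interval,
    n = sim$n, per = per,
    cases_noscreen = u$cancer_cases * f,
    cases_screen = s$cancer_cases * f,
    case_reduction_pct = 100 * (1 - s$cancer_cases / u$cancer_cases),
    deaths_noscreen = u$pc_deaths * f,
    deaths_screen = s$pc_deaths * f,
    death_reduction_pct = 100 * (1 - s$pc_deaths / u$pc_deaths),
    incidence_noscreen = inc_u, incidence_screen = inc_s,
    incidence_reduction_pct = 100 * (1 - inc_s / inc_u),
    mortality_noscreen = mort_u, mortality_screen = mort_s,
    mortality_reduction_pct = 100 * (1 - mort_s / mort_u),
    screen_tests = s$screen_tests * f,
    surveillance_tests = s$surveillance_tests * f,
    resections = s$resections * f,
    total_resections = s$total_resections * f,
    sd_cases = c(I = s$cases_sd_I, II = s$cases_sd_II,
                 III_IV = s$cases_sd_III_IV) * f,
    lyg = sim$life_years_gained * f,
    interval_cancers_5y_rate = rate_per_100k(s$interval_cancers_5y,
                                             s$person_years),
    interval_cancers_total_rate = rate_per_100k(s$interval_cancers_total,
                                                s$person_years),
    deaths_prevented = eff$deaths_prevented * f,
    NNS = eff$NNS, NNSurv = eff$NNSurv, NNT = eff$NNT)
  class(out) <- "outcome_table"
  out
}

#' @export
print.outcome_table <- function(x, digits = 1, ...) {
  cat(sprintf("Screening outcomes: %s pathway, %g-year interval (per %s persons)\n",
              x$pathway, x$interval, format(x$per, big.mark = ",")))
  cat(sprintf("  Cancer cases      %8.0f -> %6.0f  (%+.1f%%)\n",
              x$cases_noscreen, x$cases_screen, -x$case_reduction_pct))
  cat(sprintf("  Cancer deaths     %8.0f -> %6.0f  (%+.1f%%)\n",
              x$deaths_noscreen, x$deaths_screen, -x$death_reduction_pct))
  cat(sprintf("  Incidence /100k LY %7.0f -> %6.0f  (%+.1f%%)\n",
              x$incidence_noscreen, x$incidence_screen,
              -x$incidence_reduction_pct))
  cat(sprintf("  Mortality /100k LY %7.0f -> %6.0f  (%+.1f%%)\n",
              x$mortality_noscreen, x$mortality_screen,
              -x$mortality_reduction_pct))
  cat(sprintf("  Screen tests %.0f; surveillance tests %.0f; resections %.0f\n",
              x$screen_tests, x$surveillance_tests, x$total_resections))
  cat(sprintf("  LYs gained %.0f; interval cancers /100k LY: %.0f (5y %.0f)\n",
              x$lyg, x$interval_cancers_total_rate,
              x$interval_cancers_5y_rate))
  cat(sprintf("  NNS %.0f   NNSurv %.1f   NNT %.1f\n", x$NNS, x$NNSurv,
              x$NNT))
  invisible(x)
}

#' Flatten outcome tables to a data frame (Table-2-like layout)
#'
#' @param tables a list of `outcome_table` objects.
#' @return data frame, one row per scenario.
#' @export
outcomes_to_df <- function(tables) {
  if (inherits(tables, "outcome_table")) tables <- list(tables)
  rows <- lapply(tables, function(x) {
    data.frame(pathway = x$pathway, interval = x$interval, n = x$n,
               cases_noscreen = x$cases_noscreen,
               cases_screen = x$cases_screen,
               deaths_noscreen = x$deaths_noscreen,
               deaths_screen = x$deaths_screen,
               death_reduction_pct = x$death_reduction_pct,
               incidence_reduction_pct = x$incidence_reduction_pct,
               mortality_reduction_pct = x$mortality_reduction_pct,
               screen_tests = x$screen_tests,
               surveillance_tests = x$surveillance_tests,
               total_resections = x$total_resections,
               lyg = x$lyg,
               interval_cancers_total_rate = x$interval_cancers_total_rate,
               NNS = x$NNS, NNSurv = x$NNSurv, NNT = x$NNT)
  })
  do.call(rbind, rows)
}
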