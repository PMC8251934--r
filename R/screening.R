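# Screening, surveillance and management.
#
# The screening overlay walks a person's scheduled screens, applies the
# stage-specific test, and routes positives through management: resection
# (with surgical mortality), six-monthly surveillance until exit, return to
# routine screening, or palliation for preclinical stage III/IV. Screening
# draws come from the person's dedicated screening stream, so the policy never
# perturbs natural-history draws.
#
# Screening-stream draw protocol (identical in the compiled engine), in event
# order:
#   - one u per test (screen or surveillance)
#   - on a positive, non-III/IV result: one u for the management decision
#   - on resection: one u for surgical death
#   - after curative resection of a preinvasive lesion: a full re-onset
#     segment is drawn eagerly (same sub-protocol as the natural history,
#     conditioned on the resection age)
#   - on screen-detection of preclinical I/II (resected) or III/IV
#     (palliated): one u for post-diagnosis survival

#' Screening policy
#'
#' @param start_age,stop_age first and last ages at which routine screens are
#'   offered (inclusive).
#' @param interval years between routine screens (1 or 5 in the base cases).
#' @param surveillance_interval years between surveillance tests after a
#'   positive screen (6 months).
#' @return object of class `screening_policy`. Adherence is complete: every
#'   scheduled test of a living, undiagnosed person is taken.
#' @export
screening_policy <- function(start_age = 50, stop_age = 75, interval = 1,
                             surveillance_interval = 0.5) {
  stopifnot(start_age < stop_age, interval > 0, surveillance_interval > 0)
  structure(list(start_age = start_age, stop_age = stop_age,
                 interval = interval,
                 surveillance_interval = surveillance_interval,
                 adherence = 1.0),
            class = "screening_policy")
}

#' Routine screen ages implied by a policy
#'
#' @param policy a [screening_policy()].
#' @return ages `start_age, start_age + interval, ... <= stop_age`.
#' @export
screen_schedule <- function(policy) {
  seq(policy$start_age, policy$stop_age, by = policy$interval)
}

#' Test characteristics
#'
#' Stage-specific sensitivity of the combined EUS/MRI-like test and a single
#' specificity for lesion-free pancreata. Surveillance tests share the screen
#' test's characteristics.
#'
#' @param sensitivity length-6 vector, stage order LGD, IGD, HGD,
#'   preclinical I, II, III/IV.
#' @param specificity probability a lesion-free pancreas tests negative.
#' @param sensitivity_multiplier scales every stage sensitivity, capped at 1
#'   (sensitivity-analysis hook).
#' @return object of class `test_characteristics`.
#' @export
test_characteristics <- function(sensitivity = c(0.60, 0.60, 0.75,
                                                 0.90, 0.93, 0.99),
                                 specificity = 0.90,
                                 sensitivity_multiplier = 1) {
  sens <- pmin(unname(sensitivity) * sensitivity_multiplier, 1)
  stopifnot(length(sens) == 6L, all(sens >= 0), all(sens <= 1),
            specificity >= 0, specificity <= 1,
            !is.unsorted(sens[4:6]))
  structure(list(sensitivity = sens, specificity = specificity),
            class = "test_characteristics")
}

#' Management policy for positive tests
#'
#' @param resect_prob_given_positive per-stage (LGD..preclinical II)
#'   probability that a positive-tested person is referred for resection
#'   rather than surveillance. Preclinical III/IV is always palliated, never
#'   resected.
#' @param resect_prob_false_positive probability a (false-) positive person
#'   without any lesion is wrongly resected.
#' @param return_prob probability a positive-tested person returns straight to
#'   routine screening instead of surveillance or surgery.
#' @param surgical_mortality probability of death at resection.
#' @param false_positive_surveillance_rounds consecutive negative surveillance
#'   tests after which a lesion-free person returns to routine screening.
#' @return object of class `management_policy`.
#' @export
management_policy <- function(resect_prob_given_positive = rep(0.9, 5),
                              resect_prob_false_positive = 0,
                              return_prob = 0,
                              surgical_mortality = 0.03,
                              false_positive_surveillance_rounds = 1L) {
  stopifnot(length(resect_prob_given_positive) == 5L,
            all(resect_prob_given_positive >= 0),
            all(resect_prob_given_positive <= 1),
            resect_prob_false_positive >= 0, resect_prob_false_positive <= 1,
            return_prob >= 0, return_prob <= 1,
            surgical_mortality >= 0, surgical_mortality < 1,
            false_positive_surveillance_rounds >= 1)
  structure(list(resect_prob = unname(resect_prob_given_positive),
                 resect_prob_none = resect_prob_false_positive,
                 return_prob = return_prob,
                 surgical_mortality = surgical_mortality,
                 fp_rounds = as.integer(false_positive_surveillance_rounds)),
            class = "management_policy")
}

#' Apply one test to a true disease stage
#'
#' @param true_stage stage code 0..6 or name; clinical disease has exited
#'   screening and is rejected.
#' @param chars a [test_characteristics()].
#' @param u uniform draw(s).
#' @return logical: test positive? A lesion-free pancreas is (falsely)
#'   positive with probability `1 - specificity`.
#' @export
apply_test <- function(true_stage, chars, u) {
  code <- if (is.character(true_stage)) STAGES[[true_stage]] else
    as.integer(true_stage)
  if (is.na(code) || code < 0L || code > 6L)
    stop("true_stage must be NONE or a preinvasive/preclinical stage")
  if (code == 0L) u < 1 - chars$specificity else u < chars$sensitivity[code]
}

#' Route a positive test through management
#'
#' @param detected_stage true stage at the positive test (0 for a false
#'   positive).
#' @param mgmt a [management_policy()].
#' @param u uniform draw.
#' @return one of `"resect"`, `"surveil"`, `"return_to_screening"`,
#'   `"palliate"` (the latter always, and only, for preclinical III/IV).
#' @export
manage_positive <- function(detected_stage, mgmt, u) {
  code <- if (is.character(detected_stage)) STAGES[[detected_stage]] else
    as.integer(detected_stage)
  if (code == 6L) return("palliate")
  pr <- if (code == 0L) mgmt$resect_prob_none else mgmt$resect_prob[code]
  pret <- if (code == 0L) 0 else mgmt$return_prob
  if (u < pr) "resect"
  else if (u < pr + pret) "return_to_screening"
  else "surveil"
}

# ---------------------------------------------------------------------------
# Reference per-person screening engine.

stage_at_age <- function(seg, t) {
  if (is.na(seg$onset) || t < seg$onset) return(0L)
  for (j in 1:6) {
    if (t >= seg$entries[j] && t < seg$entries[j] + seg$durations[j])
      return(j)
  }
  0L # unreachable for a live, undiagnosed lesion; defensive
}

#' Simulate one person's screened life history (reference implementation)
#'
#' Interpreted, event-by-event application of a screening policy to one
#' person, consuming the identical counter-based streams as the compiled
#' engine; used as its independent cross-check and for event-log inspection.
#'
#' @inheritParams build_disease_course
#' @param policy a [screening_policy()].
#' @param chars a [test_characteristics()].
#' @param mgmt a [management_policy()].
#' @return a list of class `screened_history`: the unscreened course plus
#'   screen/surveillance test ages, resections, screen detection, surgical
#'   death flag, and the modified final death age and cause (`"other"`,
#'   `"pancreatic_cancer"` or `"surgical"`).
#' @export
simulate_screened_history <- function(config, table, seed, person,
                                      policy = screening_policy(),
                                      chars = test_characteristics(),
                                      mgmt = management_policy()) {
  nh <- ps_stream_env(seed, person, 1L)
  ocd <- lt_inverse(table$survival, ps_draw(nh))
  seg <- nh_segment(config, nh)
  scr <- ps_stream_env(seed, person, 2L)

  sched <- screen_schedule(policy)
  nsched <- length(sched)
  k <- 1L
  surveilling <- FALSE
  tnext <- NA_real_
  consec <- 0L
  cur <- seg
  res <- list(screen_test_ages = numeric(0),
              surveillance_test_ages = numeric(0),
              resections = integer(6),      # index 1:5 by stage; 6 = lesion-free
              resection_ages = numeric(0), resection_stages = integer(0),
              screen_dx_age = NA_real_, screen_dx_stage = NA_integer_,
              clinical_dx_age = NA_real_, clinical_dx_stage = NA_integer_,
              surgical_death = FALSE, pc_death_age = NA_real_,
              last_negative_screen = NA_real_)
  surg_age <- NA_real_
  exited <- FALSE

  advance_k <- function(t) { while (k <= nsched && sched[k] <= t) k <<- k + 1L }

  repeat {
    if (!surveilling) {
      if (k > nsched) break
      t <- sched[k]
    } else t <- tnext
    # pending clinical diagnosis?
    if (!is.na(cur$dx_age) && cur$dx_age <= t && cur$dx_age < ocd) {
      res$clinical_dx_age <- cur$dx_age
      res$clinical_dx_stage <- cur$dx_stage
      res$pc_death_age <- cur$pc_death
      exited <- TRUE
      break
    }
    if (t >= ocd) break
    s <- stage_at_age(cur, t)
    u <- ps_draw(scr)
    pos <- if (s == 0L) u < 1 - chars$specificity else u < chars$sensitivity[s]
    if (!surveilling) res$screen_test_ages <- c(res$screen_test_ages, t)
    else res$surveillance_test_ages <- c(res$surveillance_test_ages, t)
    if (!pos) {
      if (!surveilling) {
        res$last_negative_screen <- t
        k <- k + 1L
      } else {
        if (s == 0L) {
          consec <- consec + 1L
          if (consec >= mgmt$fp_rounds) {
            surveilling <- FALSE
            advance_k(t)
          } else tnext <- t + policy$surveillance_interval
        } else {
          consec <- 0L
          tnext <- t + policy$surveillance_interval
        }
      }
      next
    }
    # positive test
    if (s == 6L) { # palliative care for screen-detected stage III/IV
      res$screen_dx_age <- t
      res$screen_dx_stage <- 6L
      u2 <- ps_draw(scr)
      res$pc_death_age <- t + u2 * 5
      exited <- TRUE
      break
    }
    pr <- if (s == 0L) mgmt$resect_prob_none else mgmt$resect_prob[s]
    pret <- if (s == 0L) 0 else mgmt$return_prob
    um <- ps_draw(scr)
    if (um < pr) {
      idx <- if (s == 0L) 6L else s
      res$resections[idx] <- res$resections[idx] + 1L
      res$resection_ages <- c(res$resection_ages, t)
      res$resection_stages <- c(res$resection_stages, s)
      us <- ps_draw(scr)
      if (us < mgmt$surgical_mortality) {
        res$surgical_death <- TRUE
        surg_age <- t
        if (s %in% 4:5) { res$screen_dx_age <- t; res$screen_dx_stage <- s }
        exited <- TRUE
        break
      }
      if (s %in% 1:3) {
        cur <- nh_segment(config, scr, current_age = t)   # back at risk
        surveilling <- FALSE
        consec <- 0L
        advance_k(t)
      } else if (s %in% 4:5) {
        res$screen_dx_age <- t
        res$screen_dx_stage <- s
        u2 <- ps_draw(scr)
        q <- 1 - config$five_year_survival[s - 3L]
        if (q > 0 && u2 < q) res$pc_death_age <- t + (u2 / q) * 5
        exited <- TRUE
        break
      } else { # wrongful resection of a lesion-free person
        surveilling <- FALSE
        consec <- 0L
        advance_k(t)
      }
    } else if (um < pr + pret) {
      surveilling <- FALSE
      consec <- 0L
      advance_k(t)
    } else {
      surveilling <- TRUE
      consec <- 0L
      tnext <- t + policy$surveillance_interval
    }
  }

  # clinical diagnosis after the screening era
  if (!exited && !is.na(cur$dx_age) && cur$dx_age < ocd) {
    res$clinical_dx_age <- cur$dx_age
    res$clinical_dx_stage <- cur$dx_stage
    res$pc_death_age <- cur$pc_death
  }
  if (!is.na(res$pc_death_age) && res$pc_death_age >= ocd)
    res$pc_death_age <- NA_real_

  res$other_cause_death_age <- ocd
  if (res$surgical_death) {
    res$final_death_age <- surg_age
    res$death_cause <- "surgical"
  } else if (!is.na(res$pc_death_age)) {
    res$final_death_age <- res$pc_death_age
    res$death_cause <- "pancreatic_cancer"
  } else {
    res$final_death_age <- ocd
    res$death_cause <- "other"
  }
  res$unscreened <- build_disease_course(config, table, seed, person)
  class(res) <- "screened_history"
  res
}

#' @export
print.screened_history <- function(x, ...) {
  cat("<screened_history>\n")
  cat("  screens:", length(x$screen_test_ages),
      " surveillance tests:", length(x$surveillance_test_ages),
      " resections:", sum(x$resections), "\n")
  if (!is.na(x$screen_dx_age))
    cat(sprintf("  screen-detected %s at %.1f\n",
                stage_name(x$screen_dx_stage), x$screen_dx_age))
  if (!is.na(x$clinical_dx_age))
    cat(sprintf("  clinical dx %s at %.1f\n",
                stage_name(x$clinical_dx_stage), x$clinical_dx_age))
  cat(sprintf("  death %.1f (%s); unscreened death %.1f (%s)\n",
              x$final_death_age, x$death_cause,
              x$unscreened$final_death_age, x$unscreened$death_cause))
  invisible(x)
}
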