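# Natural history: the unscreened disease course.
#
# Per-person draw protocol on the natural-history stream (identical in the
# compiled engine):
#   1. u -> other-cause death age (life-table inverse CDF)
#   2. u -> lesion onset age (Weibull cumulative hazard); onset at or beyond
#        max_age counts as "never develops a lesion", and in that case no
#        further natural-history draws are consumed
#   3. u -> lesion fate (indolent with probability indolent_fraction)
#   4. one shared quantile v (rho = 1) or 7 uniforms (Gaussian copula) ->
#        exponential stage durations
#   5. progressive fate only: one u per preclinical stage reached, combining
#        the clinical-detection Bernoulli and the (uniform) detection time:
#        detected iff u < p_stage, at fraction u/p_stage of the dwell
#   6. if diagnosed: one u combining the survival Bernoulli and the (uniform
#        over 5 years) time of cancer death: fatal iff u < 1 - S5, at
#        (u / (1 - S5)) * 5 years after diagnosis
# The full disease timeline is generated without reference to the death age;
# truncation at other-cause death happens when outcomes are read off. This
# keeps stream consumption identical across arms and policies.

#' Sample a lesion onset age
#'
#' Inverse-CDF draw from the Weibull onset hazard
#' `Lambda(a) = rate * (a / sigma)^shape`, optionally conditioned on being
#' lesion-free at `current_age` (used for re-onset after curative resection).
#'
#' @param config a [pathway_config()] with calibrated `onset_rate`.
#' @param u uniform draw(s) in `[0, 1)`.
#' @param current_age condition on no onset before this age.
#' @return onset age in years; `NA` when the person never develops a lesion
#'   (onset beyond the life-table horizon). Vectorised over `u`.
#' @export
sample_onset_age <- function(config, u, current_age = 0) {
  if (is.na(config$onset_rate))
    stop("pathway_config is uncalibrated: onset_rate is NA; ",
         "run calibrate_onset_scale() or use a shipped preset")
  rate <- config$onset_rate
  if (rate == 0) return(rep(NA_real_, length(u)))
  sg <- config$onset_sigma
  lam0 <- rate * (current_age / sg)^config$onset_shape
  a <- sg * ((lam0 - log1p(-u)) / rate)^(1 / config$onset_shape)
  a[a >= 110] <- NA_real_
  a
}

#' Assign a lesion fate
#'
#' @inheritParams sample_onset_age
#' @return `"indolent"` with probability `indolent_fraction`, else
#'   `"progressive"`.
#' @export
assign_lesion_fate <- function(config, u) {
  ifelse(u < config$indolent_fraction, "indolent", "progressive")
}

#' Sample correlated stage durations
#'
#' A single shared quantile `v` is pushed through each stage's exponential
#' inverse CDF (`d = -mean * log(1 - v)`), giving perfect rank correlation
#' across consecutive stages. An indolent lesion uses the indolent means and
#' an unbounded preclinical-I dwell.
#'
#' @inheritParams sample_onset_age
#' @param fate `"progressive"` or `"indolent"`.
#' @param v shared quantile in `(0, 1)`.
#' @return numeric vector of 6 stage durations (years), in stage order; for an
#'   indolent lesion entries 4:6 are `Inf` (preclinical I is absorbing and
#'   stages II/III-IV unreachable).
#' @export
sample_stage_durations <- function(config, fate, v) {
  stopifnot(v > 0, v < 1)
  if (fate == "progressive") {
    -config$progressive_stage_means * log1p(-v)
  } else {
    c(-config$indolent_stage_means * log1p(-v), Inf, Inf, Inf)
  }
}

#' Sample clinical detection within a preclinical stage
#'
#' With the stage's clinical-diagnosis probability, symptoms surface at a
#' uniform time within the dwell; the single uniform `u` supplies both the
#' Bernoulli and the time (`u / p` is uniform on `(0, 1)` conditional on
#' detection).
#'
#' @param stage stage code (4, 5 or 6) or name (`"PRECLIN_I"`, ...).
#' @param dwell stage dwell time in years.
#' @inheritParams sample_onset_age
#' @return detection time within the stage (years from stage entry), or `NA`
#'   if the lesion leaves the stage undetected.
#' @export
sample_clinical_detection <- function(stage, dwell, config, u) {
  code <- if (is.character(stage)) STAGES[[stage]] else as.integer(stage)
  if (!code %in% 4:6)
    stop("clinical detection applies to preclinical cancer stages only")
  p <- config$clinical_dx_prob[code - 3L]
  ifelse(u < p, (u / p) * dwell, NA_real_)
}

#' Sample survival after cancer diagnosis
#'
#' With probability `1 - S5[stage]` the person dies of pancreatic cancer at a
#' uniform time within 5 years of diagnosis (linear mortality); otherwise the
#' person is cured (lifelong survival). Applies equally to clinically and
#' screen-detected invasive cancer.
#'
#' @param stage_at_dx stage at diagnosis: code 4:6 / name, or clinical stage
#'   label `"CLINICAL_I"`, `"CLINICAL_II"`, `"CLINICAL_III_IV"`.
#' @inheritParams sample_onset_age
#' @return years from diagnosis to cancer death, or `NA` if cured.
#' @export
sample_pc_survival <- function(stage_at_dx, config, u) {
  idx <- pc_stage_index(stage_at_dx)
  q <- 1 - config$five_year_survival[idx]
  if (q <= 0) return(rep(NA_real_, length(u)))
  ifelse(u < q, (u / q) * 5, NA_real_)
}

pc_stage_index <- function(stage) {
  if (is.character(stage)) {
    map <- c(CLINICAL_I = 1L, CLINICAL_II = 2L, CLINICAL_III_IV = 3L,
             PRECLIN_I = 1L, PRECLIN_II = 2L, PRECLIN_III_IV = 3L)
    idx <- map[[stage]]
  } else {
    code <- as.integer(stage)
    if (!code %in% 4:6) stop("invalid cancer stage")
    idx <- code - 3L
  }
  idx
}

# ---------------------------------------------------------------------------
# Reference (interpreted) course builder. Consumes draws from a stream
# environment following the protocol above. `current_age` > 0 builds a
# re-onset segment (screening module).
nh_segment <- function(config, stream, current_age = 0) {
  seg <- list(onset = NA_real_, fate = NA_character_,
              entries = rep(NA_real_, 6), durations = rep(NA_real_, 6),
              dx_age = NA_real_, dx_stage = NA_integer_,
              pc_death = NA_real_)
  u <- ps_draw(stream)
  rate <- config$onset_rate
  if (rate == 0) return(seg)
  sg <- config$onset_sigma
  lam0 <- rate * (current_age / sg)^config$onset_shape
  onset <- sg * ((lam0 - log1p(-u)) / rate)^(1 / config$onset_shape)
  if (onset >= 110) return(seg)
  seg$onset <- onset
  seg$fate <- if (ps_draw(stream) < config$indolent_fraction)
    "indolent" else "progressive"
  if (config$rho >= 1) {
    v <- ps_draw(stream)
    vs <- rep(v, 6)
  } else {
    z0 <- stats::qnorm(ps_draw(stream))
    vs <- vapply(1:6, function(j) {
      zj <- stats::qnorm(ps_draw(stream))
      stats::pnorm(sqrt(config$rho) * z0 + sqrt(1 - config$rho) * zj)
    }, numeric(1))
  }
  means <- if (seg$fate == "progressive") config$progressive_stage_means else
    c(config$indolent_stage_means, Inf, Inf, Inf)
  seg$durations <- -means * log1p(-vs)
  seg$durations[is.nan(seg$durations)] <- Inf
  e <- onset
  for (j in 1:6) {
    seg$entries[j] <- e
    e <- e + seg$durations[j]
  }
  if (seg$fate == "progressive") {
    for (j in 4:6) {
      u <- ps_draw(stream)
      p <- config$clinical_dx_prob[j - 3L]
      if (u < p) {
        seg$dx_stage <- j
        seg$dx_age <- seg$entries[j] + (u / p) * seg$durations[j]
        break
      }
    }
    # survival draw (stage III/IV guarantees diagnosis, so always reached)
    u <- ps_draw(stream)
    q <- 1 - config$five_year_survival[seg$dx_stage - 3L]
    if (q > 0 && u < q) seg$pc_death <- seg$dx_age + (u / q) * 5
  }
  seg
}

#' Build one person's unscreened disease course (reference implementation)
#'
#' Interpreted, event-by-event construction of a single unscreened life
#' history from the person's natural-history stream. The compiled engine
#' implements the identical protocol; this function exists as its independent
#' cross-check and for inspection of individual histories.
#'
#' @param config a calibrated [pathway_config()].
#' @param table a [life_table()].
#' @param seed scenario seed.
#' @param person 1-based person index.
#' @return a list of class `disease_course`: onset/fate/stage entries,
#'   clinical diagnosis, cancer death, other-cause death, final death age and
#'   cause (`"other"` or `"pancreatic_cancer"`). Disease events after the
#'   other-cause death age are truncated (`NA`).
#' @export
build_disease_course <- function(config, table, seed, person) {
  stream <- ps_stream_env(seed, person, 1L)
  ocd <- lt_inverse(table$survival, ps_draw(stream))
  seg <- nh_segment(config, stream)
  course <- list(onset_age = seg$onset, lesion_fate = seg$fate,
                 stage_entry_ages = seg$entries,
                 stage_durations = seg$durations,
                 clinical_dx_age = seg$dx_age, clinical_dx_stage = seg$dx_stage,
                 pc_death_age = seg$pc_death,
                 other_cause_death_age = ocd)
  # truncate at other-cause death
  if (!is.na(course$onset_age) && course$onset_age >= ocd) {
    course[c("onset_age", "lesion_fate", "clinical_dx_age",
             "clinical_dx_stage", "pc_death_age")] <-
      list(NA_real_, NA_character_, NA_real_, NA_integer_, NA_real_)
    course$stage_entry_ages <- rep(NA_real_, 6)
    course$stage_durations <- rep(NA_real_, 6)
  }
  if (!is.na(course$clinical_dx_age) && course$clinical_dx_age >= ocd) {
    course$clinical_dx_age <- NA_real_
    course$clinical_dx_stage <- NA_integer_
    course$pc_death_age <- NA_real_
  }
  if (!is.na(course$pc_death_age) && course$pc_death_age >= ocd)
    course$pc_death_age <- NA_real_
  course$final_death_age <- min(course$pc_death_age, ocd, na.rm = TRUE)
  course$death_cause <- if (!is.na(course$pc_death_age))
    "pancreatic_cancer" else "other"
  class(course) <- "disease_course"
  course
}

#' @export
print.disease_course <- function(x, ...) {
  cat("<disease_course>\n")
  if (is.na(x$onset_age)) {
    cat("  no lesion;")
  } else {
    cat(sprintf("  onset %.1f (%s)", x$onset_age, x$lesion_fate))
    if (!is.na(x$clinical_dx_age))
      cat(sprintf("; clinical dx %.1f at %s", x$clinical_dx_age,
                  stage_name(x$clinical_dx_stage)))
    cat(";")
  }
  cat(sprintf(" death %.1f (%s)\n", x$final_death_age, x$death_cause))
  invisible(x)
}
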