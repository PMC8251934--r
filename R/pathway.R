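# Disease stages and pathway configuration.
#
# Stage coding used throughout (and inside the compiled engine):
#   0 NONE, 1 LGD, 2 IGD, 3 HGD, 4 preclinical I, 5 preclinical II,
#   6 preclinical III/IV. Clinical states are exits, not standing stages.

#' Stage codes
#' @export
STAGES <- c(NONE = 0L, LGD = 1L, IGD = 2L, HGD = 3L,
            PRECLIN_I = 4L, PRECLIN_II = 5L, PRECLIN_III_IV = 6L)

stage_name <- function(code) names(STAGES)[match(code, STAGES)]

#' Pathway configuration
#'
#' Bundles the natural-history parameters of one progression hypothesis.
#' Two presets mirror the model's base cases:
#'
#' * `progressive_only`: every lesion progresses to clinical cancer; stage
#'   dwell means (years) 3.33/3.33/3.33 for LGD/IGD/HGD and 2/2/1 for
#'   preclinical I/II/III-IV (mean total preclinical 14.3 years).
#' * `indolent_included`: a fraction of lesions is indolent (dwell means
#'   7.08/11.78/24.15 preinvasive, then preclinical I until death from other
#'   causes, never lethal); progressive lesions are fast
#'   (1.11/1.11/1.11/0.66/0.66/0.33, mean total preclinical 4.8 years).
#'
#' Stage durations are exponential (Weibull with shape 1); one shared quantile
#' per lesion makes consecutive stage durations perfectly rank-correlated
#' (a lesion fast in one stage is fast in the next); `rho < 1` relaxes this
#' through a Gaussian copula.
#'
#' Lesion onset follows a Weibull cumulative hazard
#' `Lambda(a) = rate * (a / 100)^shape`; `rate` is the free parameter tuned by
#' [calibrate_onset_scale()] and `shape` controls how steeply onset (and hence
#' stage prevalence) rises with age.
#'
#' @param pathway_name `"progressive_only"` or `"indolent_included"`.
#' @param progressive_stage_means dwell-time means (years) for the six stages
#'   of a progressive lesion, in stage order LGD..preclinical III/IV.
#' @param indolent_stage_means dwell-time means for an indolent lesion's
#'   LGD/IGD/HGD stages; its preclinical-I dwell is unbounded (absorbing until
#'   other-cause death).
#' @param indolent_fraction probability that a new lesion is indolent.
#' @param clinical_dx_prob probability of clinical diagnosis before leaving
#'   each preclinical stage (I, II, III/IV).
#' @param five_year_survival stage-specific 5-year relative survival after
#'   clinical (or screen) diagnosis (I, II, III/IV); mortality is linear over
#'   the 5 years and survivors are cured.
#' @param onset_rate,onset_shape onset-hazard parameters (see above);
#'   `onset_rate = NA` marks an uncalibrated configuration.
#' @param rho rank-correlation parameter for consecutive stage durations
#'   (1 = one shared quantile).
#' @param lifetime_risk_target nominal lifetime clinical-cancer risk the
#'   pathway is associated with (documentation of intent; calibration targets
#'   are set in [calibration_target()]).
#' @return an object of class `pathway_config`.
#' @export
pathway_config <- function(pathway_name,
                           progressive_stage_means,
                           indolent_stage_means = NULL,
                           indolent_fraction = 0,
                           clinical_dx_prob = c(I = 0.051, II = 0.131,
                                                III_IV = 1.0),
                           five_year_survival = c(I = 0.291, II = 0.114,
                                                  III_IV = 0.0),
                           onset_rate = NA_real_, onset_shape = 5,
                           rho = 1,
                           lifetime_risk_target = 0.075) {
  stopifnot(length(progressive_stage_means) == 6L,
            all(progressive_stage_means > 0),
            indolent_fraction >= 0, indolent_fraction <= 1,
            length(clinical_dx_prob) == 3L,
            all(clinical_dx_prob >= 0), all(clinical_dx_prob <= 1),
            clinical_dx_prob[3] == 1,
            length(five_year_survival) == 3L,
            all(five_year_survival >= 0), all(five_year_survival < 1),
            rho >= 0, rho <= 1, onset_shape > 0)
  if (indolent_fraction > 0 && is.null(indolent_stage_means))
    stop("indolent_stage_means required when indolent_fraction > 0")
  if (is.null(indolent_stage_means)) indolent_stage_means <- c(NA, NA, NA)
  structure(list(
    pathway_name = pathway_name,
    progressive_stage_means = unname(progressive_stage_means),
    indolent_stage_means = unname(indolent_stage_means[1:3]),
    indolent_fraction = indolent_fraction,
    clinical_dx_prob = unname(clinical_dx_prob),
    five_year_survival = unname(five_year_survival),
    onset_rate = onset_rate,
    onset_shape = onset_shape,
    onset_sigma = 100,
    rho = rho,
    lifetime_risk_target = lifetime_risk_target
  ), class = "pathway_config")
}

#' @export
print.pathway_config <- function(x, ...) {
  cat("<pathway_config>", x$pathway_name, "\n")
  cat("  progressive dwell means:",
      paste(format(x$progressive_stage_means), collapse = " "), "\n")
  if (x$indolent_fraction > 0)
    cat("  indolent fraction:", format(x$indolent_fraction),
        " dwell means:", paste(format(x$indolent_stage_means), collapse = " "),
        "+ preclinical I until death\n")
  cat("  onset: rate", format(x$onset_rate), "shape", x$onset_shape,
      if (is.na(x$onset_rate)) "(uncalibrated)" else "", "\n")
  invisible(x)
}

#' Shipped pathway presets
#'
#' `progressive_only()` and `indolent_included()` return the two base-case
#' configurations with onset parameters already calibrated (see the package
#' vignette for the calibration targets and procedure). Raw, uncalibrated
#' versions are available with `calibrated = FALSE`.
#'
#' @param calibrated if `TRUE`, fill in the packaged calibrated onset rate
#'   (and indolent fraction).
#' @return a [pathway_config()].
#' @export
progressive_only <- function(calibrated = TRUE) {
  cfg <- pathway_config(
    "progressive_only",
    progressive_stage_means = c(3.33, 3.33, 3.33, 2, 2, 1))
  if (calibrated) {
    p <- preset_parameters("progressive_only")
    cfg$onset_rate <- p$onset_rate
  }
  cfg
}

#' @rdname progressive_only
#' @export
indolent_included <- function(calibrated = TRUE) {
  p <- if (calibrated) preset_parameters("indolent_included") else
    list(onset_rate = NA_real_, indolent_fraction = 0.5)
  pathway_config(
    "indolent_included",
    progressive_stage_means = c(1.11, 1.11, 1.11, 0.66, 0.66, 0.33),
    indolent_stage_means = c(7.08, 11.78, 24.15),
    indolent_fraction = p$indolent_fraction,
    onset_rate = p$onset_rate)
}

# Calibrated parameter values shipped with the package (YAML under extdata);
# regenerated by data-raw/calibrate-presets.R.
preset_parameters <- function(name) {
  key <- paste0("preset_", name)
  if (is.null(.pancscreen_cache[[key]])) {
    path <- system.file("extdata", paste0(name, ".yaml"),
                        package = "pancscreen", mustWork = TRUE)
    .pancscreen_cache[[key]] <- yaml::read_yaml(path)
  }
  .pancscreen_cache[[key]]
}

#' Read a pathway configuration from YAML
#'
#' Keys mirror the constructor arguments of [pathway_config()].
#'
#' @param path YAML file path.
#' @return a [pathway_config()].
#' @export
read_pathway_config <- function(path) {
  y <- yaml::read_yaml(path)
  pathway_config(
    pathway_name = y$pathway_name,
    progressive_stage_means = as.numeric(y$progressive_stage_means),
    indolent_stage_means = if (!is.null(y$indolent_stage_means))
      as.numeric(y$indolent_stage_means),
    indolent_fraction = y$indolent_fraction %||% 0,
    clinical_dx_prob = if (!is.null(y$clinical_dx_prob))
      as.numeric(y$clinical_dx_prob) else c(0.051, 0.131, 1.0),
    five_year_survival = if (!is.null(y$five_year_survival))
      as.numeric(y$five_year_survival) else c(0.291, 0.114, 0.0),
    onset_rate = y$onset_rate %||% NA_real_,
    onset_shape = y$onset_shape %||% 3,
    rho = y$rho %||% 1,
    lifetime_risk_target = y$lifetime_risk_target %||% 0.075)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
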