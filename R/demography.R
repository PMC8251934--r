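# Other-cause (all-cause, pancreatic-cancer-free) mortality.
#
# Death ages absent pancreatic cancer are drawn from a life table: cumulative
# survival at exact integer ages from birth, interpolated linearly within
# years so death ages are continuous. The shipped default is a two-parameter
# Gompertz-Makeham-style table fitted to two anchors: life expectancy at birth
# and survival to the screening start age.

#' Construct a life table
#'
#' @param survival numeric vector of cumulative survival probabilities at exact
#'   integer ages `0, 1, ..., max_age`. Must start at 1, be non-increasing and
#'   end at 0.
#' @return an object of class `life_table`.
#' @examples
#' lt <- life_table(c(1, 0.9, 0.4, 0))
#' survival_to_age(lt, 1.5)
#' @export
life_table <- function(survival) {
  survival <- as.numeric(survival)
  if (length(survival) < 2L) stop("life table needs at least two ages")
  if (abs(survival[1] - 1) > 1e-12) stop("survival at age 0 must equal 1")
  if (any(diff(survival) > 1e-12)) stop("survival must be non-increasing in age")
  if (abs(survival[length(survival)]) > 1e-12)
    stop("survival at max_age must equal 0")
  survival[1] <- 1
  survival[length(survival)] <- 0
  structure(list(survival = survival, max_age = length(survival) - 1L),
            class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  e0 <- life_expectancy(x)
  cat("<life_table> max_age:", x$max_age,
      sprintf(" e0: %.2f  S(50): %.4f\n", e0,
              if (x$max_age >= 50) survival_to_age(x, 50) else NA_real_))
  invisible(x)
}

#' Cumulative survival at a (possibly fractional) age
#'
#' Linear interpolation of the life table between integer ages.
#'
#' @param table a [life_table()].
#' @param age age in years, `0 <= age <= max_age`. Vectorised.
#' @return survival probability.
#' @export
survival_to_age <- function(table, age) {
  stopifnot(inherits(table, "life_table"))
  if (any(age < 0 | age > table$max_age))
    stop("age out of range [0, ", table$max_age, "]")
  k <- pmin(floor(age), table$max_age - 1L)
  frac <- age - k
  s <- table$survival
  s[k + 1L] + frac * (s[k + 2L] - s[k + 1L])
}

#' Life expectancy at birth implied by a life table
#'
#' Integral of the survival curve (trapezoidal under linear interpolation).
#'
#' @inheritParams survival_to_age
#' @return years.
#' @export
life_expectancy <- function(table) {
  s <- table$survival
  sum((s[-1] + s[-length(s)]) / 2)
}

#' Sample a death age by inverse-CDF
#'
#' `u` is the survival quantile: the death age is the age at which cumulative
#' survival falls to `u`, interpolated within the year. Small `u` therefore
#' maps to old ages (`u -> 0` approaches `max_age`), and the draw is
#' deterministic given `u`.
#'
#' @inheritParams survival_to_age
#' @param u uniform draw(s) in `[0, 1)`.
#' @return death age in years (continuous). Vectorised over `u`.
#' @export
sample_death_age <- function(table, u) {
  stopifnot(inherits(table, "life_table"))
  if (any(u < 0 | u >= 1)) stop("u must lie in [0, 1)")
  vapply(u, function(ui) lt_inverse(table$survival, ui), numeric(1))
}

# Inverse survival with linear interpolation; mirrored verbatim in the
# compiled engine.
lt_inverse <- function(s, u) {
  n <- length(s)
  if (u >= s[2]) {
    k <- 0L
  } else {
    lo <- 2L; hi <- n
    # largest k (0-based) with s[k+1] > u
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (s[mid] > u) lo <- mid else hi <- mid
    }
    k <- lo - 1L
  }
  drop_ <- s[k + 1L] - s[k + 2L]
  frac <- if (drop_ > 0) (s[k + 1L] - u) / drop_ else 1
  k + frac
}

#' Fit a Gompertz-Makeham-style life table to two anchors
#'
#' Hazard model: `mu(a) = A + B * exp(theta * a)` with a small fixed Makeham
#' background `A`. Given `theta`, `B` is solved so that survival to age 50
#' matches `target_survival_50`; `theta` is then solved so that the life
#' expectancy of the (truncated, max_age-conditioned) table matches
#' `target_life_expectancy`. Matching is within 0.5% relative on both targets.
#'
#' @param target_life_expectancy years, in `(0, max_age)`.
#' @param target_survival_50 probability of surviving to age 50, in `(0, 1)`.
#' @param max_age oldest attainable age (survival forced to 0 there).
#' @param makeham fixed background hazard `A` (per year).
#' @return a calibrated [life_table()], with the fitted parameters attached as
#'   attribute `params`.
#' @examples
#' lt <- fit_life_table(69.7, 0.925)
#' life_expectancy(lt)
#' @export
fit_life_table <- function(target_life_expectancy, target_survival_50,
                           max_age = 110L, makeham = 6e-4) {
  if (target_survival_50 <= 0 || target_survival_50 >= 1)
    stop("target_survival_50 must lie in (0, 1)")
  if (target_life_expectancy <= 0 || target_life_expectancy >= max_age)
    stop("target_life_expectancy must lie in (0, max_age)")
  h50 <- -log(target_survival_50)      # required cumulative hazard to 50
  if (h50 <= makeham * 50)
    stop("infeasible target pair: background hazard alone exceeds the ",
         "survival-to-50 target")

  table_for_theta <- function(theta) {
    # B from the survival-to-50 constraint: int_0^50 B e^{theta a} da
    B <- (h50 - makeham * 50) * theta / (exp(theta * 50) - 1)
    ages <- 0:max_age
    H <- makeham * ages + B * (exp(theta * ages) - 1) / theta
    s <- exp(-H)
    # condition on death by max_age
    s <- (s - s[length(s)]) / (1 - s[length(s)])
    s[length(s)] <- 0
    life_table(s)
  }
  obj <- function(theta) life_expectancy(table_for_theta(theta)) -
    target_life_expectancy
  # e0(theta) is unimodal under the survival-to-50 constraint; scan a grid
  # for a sign change and take the steepest (largest-theta) bracket, which
  # corresponds to a realistically steep old-age hazard.
  grid <- exp(seq(log(0.02), log(0.6), length.out = 30))
  fg <- vapply(grid, obj, numeric(1))
  ix <- which(fg[-1] * fg[-length(fg)] <= 0)
  if (!length(ix))
    stop(sprintf(paste0("life-table fit did not converge: attainable life ",
                        "expectancy range [%.1f, %.1f] does not include ",
                        "%.1f at survival-to-50 = %.3f"),
                 min(fg) + target_life_expectancy,
                 max(fg) + target_life_expectancy,
                 target_life_expectancy, target_survival_50))
  i <- ix[length(ix)]
  theta <- stats::uniroot(obj, grid[c(i, i + 1L)], tol = 1e-9)$root
  lt <- table_for_theta(theta)
  achieved_e0 <- life_expectancy(lt)
  achieved_s50 <- survival_to_age(lt, 50)
  if (abs(achieved_e0 / target_life_expectancy - 1) > 0.005 ||
      abs(achieved_s50 / target_survival_50 - 1) > 0.005)
    stop("life-table fit did not reach its targets within 0.5% relative")
  B <- (h50 - makeham * 50) * theta / (exp(theta * 50) - 1)
  attr(lt, "params") <- c(makeham = makeham, B = B, theta = theta)
  lt
}

# Default table, fitted once per session. The two anchors are the cohort
# facts the model must reproduce: ~92.5% of persons alive at the screening
# start age and ~69.7 simulated life-years per person.
.pancscreen_cache <- new.env(parent = emptyenv())

#' Default life table used by the shipped presets
#'
#' @return a [life_table()] with life expectancy 69.7 years and survival to
#'   age 50 of 0.925.
#' @export
default_life_table <- function() {
  if (is.null(.pancscreen_cache$lt))
    .pancscreen_cache$lt <- fit_life_table(69.7, 0.925)
  .pancscreen_cache$lt
}

#' Read / write a life table as two-column CSV
#'
#' The file format is `age, cumulative_survival` with a header, one row per
#' integer age from 0 to `max_age`.
#'
#' @param path file path.
#' @return [life_table()] for the reader; invisibly the path for the writer.
#' @export
read_life_table <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("age", "cumulative_survival") %in% names(d)))
    stop("life-table CSV needs columns 'age' and 'cumulative_survival'")
  d <- d[order(d$age), ]
  if (!identical(as.integer(d$age), seq.int(0L, nrow(d) - 1L)))
    stop("life-table CSV must cover consecutive integer ages from 0")
  life_table(d$cumulative_survival)
}

#' @rdname read_life_table
#' @param table a [life_table()] to write.
#' @export
write_life_table <- function(table, path) {
  stopifnot(inherits(table, "life_table"))
  utils::write.csv(
    data.frame(age = 0:table$max_age, cumulative_survival = table$survival),
    path, row.names = FALSE)
  invisible(path)
}
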