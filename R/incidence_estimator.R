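# Annual incidence rates, cumulative incidence by annual recursion, by
# Nelson-Aalen with Poisson uncertainty, and by a Poisson score interval.

REPORT_AGES <- seq(25L, 70L, by = 5L)

#' Annual incidence rates per band
#'
#' The annual incidence rate (AIR) of a band is its event count divided by
#' its person-years. A band with no exposure and no events has rate zero; a
#' band with events but no exposure is invariant-violating input and raises
#' an error naming the band.
#'
#' @param table a [persontime_table()].
#' @return Numeric vector of length 9 (units 1/year), named by band.
#' @export
band_air <- function(table) {
  stopifnot(inherits(table, "persontime_table"))
  undef <- table$person_years <= 0 & table$events > 0
  if (any(undef)) {
    stop("events without person-years in band ",
         paste(band_label(table$band_start[undef]), collapse = ", "),
         call. = FALSE)
  }
  air <- ifelse(table$person_years > 0, table$events / table$person_years, 0)
  setNames(air, band_label(table$band_start))
}

#' Five-year incidence risk per band
#'
#' The band risk approximation `IR = AIR x 5`, capped at 1.
#'
#' @param air numeric vector of annual rates.
#' @return Numeric vector of band risks.
#' @export
band_ir <- function(air) pmin(1, air * 5)

#' Cumulative incidence by the annual recursion
#'
#' Steps `Q(age) = Q(age - 1) + (1 - Q(age - 1)) * AIR(age)` annually from
#' `Q(25) = 0`, where `AIR(age)` is the rate of the band containing
#' `[age - 1, age)`. Equivalently `Q(a) = 1 - prod(1 - AIR)` over elapsed
#' years, to which the stepping is exactly equal.
#'
#' @param air numeric vector of 9 per-band annual rates, each in `[0, 1]`.
#' @param ages integer ages at which to return `Q`; default every year from
#'   25 to 70.
#' @return Named numeric vector `Q(age)`, clipped to `[0, 1]`.
#' @export
cumulative_recursion <- function(air, ages = 25:70) {
  air <- as.numeric(air)
  if (length(air) != 9L) stop("need 9 per-band annual rates", call. = FALSE)
  if (any(!is.finite(air)) || any(air < 0 | air > 1)) {
    stop("annual rates must lie in [0, 1]", call. = FALSE)
  }
  grid <- 25:70
  q <- numeric(length(grid))
  for (i in seq_along(grid)[-1L]) {
    a <- grid[i]
    rate <- air[(a - 1L - 25L) %/% 5L + 1L]
    q[i] <- q[i - 1L] + (1 - q[i - 1L]) * rate
  }
  q <- pmin(pmax(q, 0), 1)
  if (!all(ages %in% grid)) {
    stop("ages must be integers in 25..70", call. = FALSE)
  }
  setNames(q[match(ages, grid)], ages)
}

# years of each band elapsed by age a, clamped to [0, 5]
elapsed_years <- function(age) pmin(pmax(age - band_starts(), 0), 5)

#' Nelson-Aalen cumulative incidence with Poisson confidence intervals
#'
#' Cumulative hazard `H(a) = sum_j AIR_j * y_j(a)` over the years `y_j(a)`
#' of each band elapsed by age `a`, with `Q(a) = 1 - exp(-H(a))`. The
#' variance of `H` uses the Poisson plug-in `Var = sum_j y_j^2 d_j / T_j^2`;
#' the confidence interval is formed on `log H` by normal approximation and
#' transformed to the incidence scale. When no events have occurred the
#' lower bound is 0 and the upper bound comes from the exact one-sided
#' Poisson bound on the total event count given the elapsed person-years;
#' with no elapsed person-years at all the interval is `[0, 0]` at age 25
#' (incidence is zero there by construction) and the vacuous `[0, 1]` later.
#'
#' @param table a [persontime_table()].
#' @param level two-sided confidence level in (0, 1); default 0.95.
#' @param report_ages ages at which to report; default 25, 30, ..., 70.
#' @return An `incidence_curve` with method `"nelson_aalen_poisson"`.
#' @export
nelson_aalen_poisson <- function(table, level = 0.95,
                                 report_ages = REPORT_AGES) {
  stopifnot(level > 0, level < 1)
  air <- band_air(table)
  z <- qnorm(1 - (1 - level) / 2)
  rate_var <- ifelse(table$person_years > 0,
                     table$events / table$person_years^2, 0)
  res <- vapply(report_ages, function(a) {
    y <- elapsed_years(a)
    H <- sum(air * y)
    V <- sum(y^2 * rate_var)
    Tel <- sum(table$person_years * y / 5)
    q <- 1 - exp(-H)
    if (H > 0) {
      se_log <- sqrt(V) / H
      lo <- 1 - exp(-H * exp(-z * se_log))
      hi <- 1 - exp(-H * exp(z * se_log))
    } else if (Tel > 0) {
      lo <- 0
      mu_up <- qgamma(1 - (1 - level) / 2, shape = 1)  # exact bound, 0 events
      hi <- 1 - exp(-(mu_up / Tel) * (a - AGE_START))
    } else {
      lo <- 0
      hi <- if (a <= AGE_START) 0 else 1
    }
    c(q, lo, min(hi, 1))
  }, numeric(3L))
  new_incidence_curve(report_ages, res[1L, ], res[2L, ], res[3L, ],
                      air = unname(air), method = "nelson_aalen_poisson",
                      stratum = attr(table, "stratum"), level = level)
}

#' Score (Lagrange-multiplier) confidence intervals for cumulative incidence
#'
#' Pools the events `D(a)` and person-years `T(a)` elapsed by each report
#' age and inverts the Poisson score statistic
#' `(D - lambda T)^2 / (lambda T) = z^2` in the annual rate `lambda`
#' (endpoints `lambda = (D + z^2/2 +/- z sqrt(D + z^2/4)) / T`). The point
#' estimate is the Nelson-Aalen cumulative incidence (which keeps the curve
#' monotone when band rates are unbalanced); the interval applies the score
#' endpoints' relative uncertainty `lambda_bound / lambda_hat` to the
#' estimated cumulative hazard, so in the single-band case the bounds are
#' exactly `Q = 1 - exp(-lambda_bound * elapsed years)` and the point
#' estimate coincides with [nelson_aalen_poisson()]. With zero events the
#' lower bound is exactly 0 and the upper bound positive.
#'
#' @inheritParams nelson_aalen_poisson
#' @return An `incidence_curve` with method `"score"`.
#' @export
score_ci <- function(table, level = 0.95, report_ages = REPORT_AGES) {
  stopifnot(level > 0, level < 1)
  air <- band_air(table)  # validates the table
  z <- qnorm(1 - (1 - level) / 2)
  res <- vapply(report_ages, function(a) {
    y <- elapsed_years(a)
    D <- sum(table$events * y / 5)
    Tel <- sum(table$person_years * y / 5)
    yrs <- a - AGE_START
    if (Tel <= 0) {
      return(c(0, 0, if (a <= AGE_START) 0 else 1))
    }
    H <- sum(air * y)
    q <- 1 - exp(-H)
    disc <- z * sqrt(D + z^2 / 4)
    lam_lo <- max(D + z^2 / 2 - disc, 0) / Tel
    lam_hi <- (D + z^2 / 2 + disc) / Tel
    if (D > 0) {
      lam_hat <- D / Tel
      c(q, 1 - exp(-H * lam_lo / lam_hat), 1 - exp(-H * lam_hi / lam_hat))
    } else {
      c(q, 0, 1 - exp(-lam_hi * yrs))
    }
  }, numeric(3L))
  new_incidence_curve(report_ages, res[1L, ], res[2L, ], res[3L, ],
                      air = unname(air), method = "score",
                      stratum = attr(table, "stratum"), level = level)
}

#' Agreement between the recursion and Nelson-Aalen point estimates
#'
#' The annual recursion compounds `1 - AIR` per year while Nelson-Aalen
#' compounds `exp(-AIR)`; the two are close to identical for small rates and
#' diverge as hazards grow. This reports the absolute discrepancy per report
#' age and flags ages exceeding a tolerance.
#'
#' @param table a [persontime_table()].
#' @param tolerance flag threshold on `|Q_recursion - Q_nelson_aalen|`;
#'   default 0.01.
#' @param report_ages ages at which to compare.
#' @return Data frame with columns `age`, `q_recursion`, `q_nelson_aalen`,
#'   `abs_diff`, `flagged`; the attribute `"max_abs_diff"` holds the sup-norm.
#' @export
compare_methods <- function(table, tolerance = 0.01,
                            report_ages = REPORT_AGES) {
  air <- band_air(table)
  q_rec <- cumulative_recursion(air, ages = report_ages)
  q_na <- vapply(report_ages,
                 function(a) 1 - exp(-sum(air * elapsed_years(a))),
                 numeric(1L))
  d <- abs(q_rec - q_na)
  out <- data.frame(age = report_ages, q_recursion = unname(q_rec),
                    q_nelson_aalen = q_na, abs_diff = unname(d),
                    flagged = unname(d > tolerance))
  attr(out, "max_abs_diff") <- max(d)
  out
}

#' Weighted mean of incidence curves
#'
#' Pointwise weighted mean of cumulative incidences across curves on an
#' identical age grid (e.g. continent-level curves pooled into a global
#' average). Confidence bounds are pooled the same way and are therefore
#' only approximate, which the result flags.
#'
#' @param curves list of `incidence_curve` objects on the same ages.
#' @param weights non-negative weights, one per curve, not all zero;
#'   normalized internally.
#' @return An `incidence_curve` with method `"weighted_mean"` and attribute
#'   `ci_pooling = "approximate"`.
#' @export
weighted_mean_curves <- function(curves, weights) {
  stopifnot(length(curves) >= 1L, length(weights) == length(curves))
  weights <- as.numeric(weights)
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative and not all zero", call. = FALSE)
  }
  ages <- curves[[1L]]$age
  for (cv in curves) {
    if (!identical(as.numeric(cv$age), as.numeric(ages))) {
      stop("curves must share an identical age grid", call. = FALSE)
    }
  }
  w <- weights / sum(weights)
  pool <- function(col) {
    Reduce(`+`, Map(function(cv, wi) wi * cv[[col]], curves, w))
  }
  airs <- lapply(curves, attr, "air")
  air <- if (any(vapply(airs, is.null, logical(1L)))) NULL else {
    Reduce(`+`, Map(`*`, airs, w))
  }
  regions <- unique(vapply(curves, function(cv) {
    attr(cv, "stratum")[["region"]]
  }, character(1L)))
  stratum <- attr(curves[[1L]], "stratum")
  stratum[["region"]] <- paste(regions, collapse = "+")
  out <- new_incidence_curve(ages, pool("q"), pool("ci_lo"), pool("ci_hi"),
                             air = air, method = "weighted_mean",
                             stratum = stratum,
                             level = attr(curves[[1L]], "level"))
  attr(out, "ci_pooling") <- "approximate"
  out
}
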