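# Synthetic carrier cohorts: piecewise-constant hazards calibratable to
# published cumulative incidences, exact piecewise-exponential event
# sampling, and replicate experiments for coverage/bias studies.

SIM_AGE_MAX <- 85  # administrative ceiling on simulated follow-up

#' Construct a hazard model
#'
#' Per-band annual CRC hazards on the nine five-year bands; the simulator's
#' ground truth. Beyond age 70 the last band's hazard is carried forward (so
#' simulated carriers can exit with post-70 events, which the person-time
#' engine must discard).
#'
#' @param lambda numeric vector of 9 non-negative annual hazards (1/year).
#' @param gene,sex,region stratum labels attached to simulated carriers.
#' @return Data frame of class `hazard_model` with columns `band_start`,
#'   `lambda` and a `"stratum"` attribute.
#' @export
hazard_model <- function(lambda, gene = "All", sex = "All", region = "All") {
  lambda <- as.numeric(lambda)
  if (length(lambda) != 9L || any(!is.finite(lambda)) || any(lambda < 0)) {
    stop("lambda must be 9 finite non-negative annual hazards", call. = FALSE)
  }
  out <- data.frame(band_start = band_starts(), lambda = lambda)
  class(out) <- c("hazard_model", "data.frame")
  attr(out, "stratum") <- c(gene = gene, sex = sex, region = region)
  out
}

#' Calibrate band hazards to cumulative-incidence targets
#'
#' Inverts the annual recursion: within each interval between consecutive
#' target ages the annual rate is constant,
#' `a = 1 - ((1 - Q_end) / (1 - Q_start))^(1 / gap_years)`, and the band
#' hazard is `lambda = -log(1 - a)`. Targets may be given at any increasing
#' subset of the band boundaries 25, 30, ..., 70 (decade-only published
#' values are typical); omitted boundaries are filled by constant-hazard
#' (geometric survival) interpolation. Feeding the result back through
#' [cumulative_recursion()] reproduces every supplied target to machine
#' precision.
#'
#' @param q_targets non-decreasing cumulative incidences in `[0, 1)`, with
#'   `Q(25) = 0`.
#' @param ages band-boundary ages of the targets; must start at 25 and end
#'   at 70. Default the full grid `25, 30, ..., 70`.
#' @param gene,sex,region stratum labels for the model.
#' @return A [hazard_model()] with attributes `"air"` (the 9 annual rates)
#'   and `"q_grid"` (targets completed onto the full boundary grid).
#' @export
calibrate_hazards <- function(q_targets, ages = seq(25, 70, by = 5),
                              gene = "All", sex = "All", region = "All") {
  q <- as.numeric(q_targets)
  ages <- as.numeric(ages)
  if (length(q) != length(ages)) {
    stop("q_targets and ages must have equal length", call. = FALSE)
  }
  if (!all(ages %in% seq(25, 70, by = 5)) || is.unsorted(ages, strictly = TRUE)) {
    stop("ages must be strictly increasing band boundaries in 25..70",
         call. = FALSE)
  }
  if (ages[1L] != 25 || ages[length(ages)] != 70) {
    stop("targets must span age 25 to age 70", call. = FALSE)
  }
  if (q[1L] != 0) stop("Q(25) must be zero", call. = FALSE)
  if (any(q >= 1) || any(q < 0)) {
    stop("targets must lie in [0, 1)", call. = FALSE)
  }
  if (is.unsorted(q)) stop("targets must be non-decreasing", call. = FALSE)
  # constant hazard between targets <=> linear log-survival in age
  log_s <- approx(ages, log(1 - q), xout = seq(25, 70, by = 5))$y
  lambda <- -diff(log_s) / 5
  lambda[lambda < 0] <- 0  # guard tiny negative rounding
  model <- hazard_model(lambda, gene = gene, sex = sex, region = region)
  attr(model, "air") <- 1 - exp(-lambda)
  attr(model, "q_grid") <- setNames(1 - exp(log_s), seq(25, 70, by = 5))
  model
}

#' True cumulative incidence implied by a hazard model
#'
#' @param model a [hazard_model()].
#' @param ages ages in `[25, 70]` at which to evaluate.
#' @return Named numeric vector `Q(age) = 1 - exp(-integrated hazard)`.
#' @export
q_from_hazard <- function(model, ages = seq(25, 70, by = 5)) {
  stopifnot(inherits(model, "hazard_model"))
  q <- vapply(ages, function(a) {
    1 - exp(-sum(model$lambda * elapsed_years(a)))
  }, numeric(1L))
  setNames(q, ages)
}

#' Simulation configuration
#'
#' @param n number of carriers to generate.
#' @param entry entry-age distribution: `list(dist = "uniform", min, max)`
#'   or `list(dist = "fixed", value)`. Default uniform on `[25, 60]`, chosen
#'   to populate all bands.
#' @param followup administrative follow-up length distribution, same specs.
#'   Default uniform on `[1.6, 15]` years (mean 8.3 years).
#' @param prevalent_fraction probability a carrier is a prevalent case
#'   (CRC before or at inclusion; flagged and excluded by the engine).
#'   Default 0.1.
#' @param under25_fraction probability an entry age is drawn uniformly on
#'   `[20, 25)` instead of from `entry`, exercising left truncation.
#'   Default 0.05.
#' @param seed mandatory integer seed; simulation is deterministic given the
#'   configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n,
                       entry = list(dist = "uniform", min = 25, max = 60),
                       followup = list(dist = "uniform", min = 1.6, max = 15),
                       prevalent_fraction = 0.1,
                       under25_fraction = 0.05,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n >= 1, prevalent_fraction >= 0, prevalent_fraction <= 1,
            under25_fraction >= 0, under25_fraction <= 1)
  check_dist_spec(entry, "entry")
  check_dist_spec(followup, "followup")
  structure(list(n = as.integer(n), entry = entry, followup = followup,
                 prevalent_fraction = prevalent_fraction,
                 under25_fraction = under25_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

check_dist_spec <- function(spec, what) {
  ok <- is.list(spec) && !is.null(spec$dist) &&
    spec$dist %in% c("uniform", "fixed") &&
    (spec$dist != "uniform" ||
       (is.numeric(spec$min) && is.numeric(spec$max) && spec$max >= spec$min)) &&
    (spec$dist != "fixed" || is.numeric(spec$value))
  if (!ok) {
    stop(sprintf("invalid %s distribution spec (use uniform{min,max} or fixed{value})",
                 what), call. = FALSE)
  }
  invisible(spec)
}

draw_spec <- function(spec, n) {
  switch(spec$dist,
         uniform = runif(n, spec$min, spec$max),
         fixed = rep(as.numeric(spec$value), n))
}

# piecewise-linear cumulative hazard from age 25, last band carried past 70
cumhaz_knots <- function(model) {
  ages <- c(seq(25, 70, by = 5), SIM_AGE_MAX)
  lam <- c(model$lambda, model$lambda[9L])
  list(age = ages, H = c(0, cumsum(lam * diff(ages))), lambda = lam)
}

cumhaz_at <- function(k, age) {
  a <- pmin(pmax(age, 25), SIM_AGE_MAX)
  i <- findInterval(a, k$age, rightmost.closed = TRUE)
  k$H[i] + k$lambda[pmin(i, length(k$lambda))] * (a - k$age[i])
}

# exact inversion of the piecewise-constant cumulative hazard; Inf when the
# target exceeds the hazard accumulated by SIM_AGE_MAX
cumhaz_invert <- function(k, target) {
  out <- rep(Inf, length(target))
  inside <- target <= k$H[length(k$H)]
  i <- findInterval(target[inside], k$H)
  # findInterval lands on the rightmost duplicated knot of any flat stretch,
  # so the following interval has positive hazard whenever target > H[i]
  age <- k$age[i] + ifelse(target[inside] > k$H[i],
                           (target[inside] - k$H[i]) / k$lambda[pmin(i, length(k$lambda))],
                           0)
  out[inside] <- age
  out
}

#' Simulate a carrier cohort from known hazards
#'
#' Deterministic given the seed. Each carrier draws an entry age (a
#' configurable fraction below 25), an administrative follow-up length, and
#' an event age by exact inversion of the piecewise-constant cumulative
#' hazard accumulated from age 25 onwards; exit is the earliest of event,
#' end of follow-up, and age 85, with death and last observation merged into
#' one censoring mechanism (the censoring rule treats them identically) and
#' labelled death with probability 0.2. Prevalent carriers are flagged
#' `prior_crc` and receive a censoring exit.
#'
#' @param model a [hazard_model()].
#' @param config a [sim_config()].
#' @return A `carrier_cohort` with attributes `"bookkeeping"` (true events
#'   and person-years per band under the engine's inclusion rules),
#'   `"truth"` (the model's cumulative incidence at the report ages) and
#'   `"config"`.
#' @export
simulate_cohort <- function(model, config) {
  stopifnot(inherits(model, "hazard_model"), inherits(config, "sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  n <- config$n
  prevalent <- runif(n) < config$prevalent_fraction
  under25 <- runif(n) < config$under25_fraction
  entry <- draw_spec(config$entry, n)
  entry[under25] <- runif(sum(under25), 20, 25)
  fu <- draw_spec(config$followup, n)
  death_label <- runif(n) < 0.2
  e_std <- rexp(n)

  k <- cumhaz_knots(model)
  event_age <- cumhaz_invert(k, cumhaz_at(k, entry) + e_std)
  censor_age <- pmin(entry + fu, SIM_AGE_MAX)
  has_event <- !prevalent & event_age < censor_age
  exit <- pmin(event_age, censor_age)
  exit[prevalent] <- censor_age[prevalent]
  reason <- ifelse(has_event, "crc_event",
                   ifelse(death_label, "death", "last_observation"))
  s <- attr(model, "stratum")
  cohort <- data.frame(carrier_id = sprintf("S%05d", seq_len(n)),
                       gene = s[["gene"]], sex = s[["sex"]],
                       region = s[["region"]],
                       entry_age = entry, exit_age = exit,
                       exit_reason = reason, prior_crc = prevalent,
                       stringsAsFactors = FALSE)
  class(cohort) <- c("carrier_cohort", "data.frame")
  attr(cohort, "bookkeeping") <- sim_bookkeeping(cohort)
  attr(cohort, "truth") <- q_from_hazard(model)
  attr(cohort, "config") <- config
  cohort
}

# band-level truth ledger for the emitted records, per the engine's rules
sim_bookkeeping <- function(cohort) {
  start <- pmax(cohort$entry_age, AGE_START)
  stop_ <- pmin(cohort$exit_age, AGE_CAP)
  keep <- !cohort$prior_crc & stop_ > start
  counts <- cohort$exit_reason == "crc_event" & cohort$exit_age <= AGE_CAP & keep
  expo <- exposure_matrix(start[keep], stop_[keep])
  d <- tabulate(event_band_index(stop_[counts]), nbins = 9L)
  data.frame(band_start = band_starts(),
             true_events = d,
             true_person_years = colSums(expo))
}

#' Replicate simulation experiment for one estimator
#'
#' Simulates `n_replicates` cohorts from a hazard model, estimates the
#' cumulative incidence and its confidence interval at a target age in each,
#' and summarizes empirical coverage of the generating truth, bias and RMSE.
#'
#' @param model a [hazard_model()].
#' @param config a [sim_config()]; its seed is the experiment's base seed.
#' @param n_replicates number of replicate cohorts.
#' @param method `"nelson_aalen_poisson"` or `"score"`.
#' @param level confidence level.
#' @param age target age (default 70).
#' @details Replicate `r` re-seeds the simulator with
#'   `(seed * 100003 + r) mod (2^31 - 1)` so that experiments launched from
#'   nearby base seeds use disjoint replicate streams.
#' @return A list of class `replicate_summary`: `truth`, `coverage`,
#'   `coverage_se` (binomial Monte-Carlo SE), `bias`, `bias_se`, `rmse`,
#'   `n_replicates`, and the per-replicate data frame `replicates`
#'   (`q`, `ci_lo`, `ci_hi`, `covered`).
#' @export
simulate_many <- function(model, config, n_replicates,
                          method = c("nelson_aalen_poisson", "score"),
                          level = 0.95, age = 70) {
  method <- match.arg(method)
  est <- switch(method, nelson_aalen_poisson = nelson_aalen_poisson,
                score = score_ci)
  truth <- unname(q_from_hazard(model, age))
  reps <- vapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- as.integer((as.double(config$seed) * 100003 + r) %%
                             .Machine$integer.max)
    cohort <- simulate_cohort(model, cfg)
    tab <- tabulate_persontime(cohort, group_by = character(0))[[1L]]
    curve <- est(tab, level = level, report_ages = c(25, age))
    i <- match(age, curve$age)
    c(curve$q[i], curve$ci_lo[i], curve$ci_hi[i])
  }, numeric(3L))
  covered <- reps[2L, ] <= truth & truth <= reps[3L, ]
  bias <- mean(reps[1L, ]) - truth
  out <- list(truth = truth,
              coverage = mean(covered),
              coverage_se = sqrt(mean(covered) * (1 - mean(covered)) /
                                   n_replicates),
              bias = bias,
              bias_se = sd(reps[1L, ]) / sqrt(n_replicates),
              rmse = sqrt(mean((reps[1L, ] - truth)^2)),
              n_replicates = n_replicates,
              method = method, level = level, age = age,
              replicates = data.frame(q = reps[1L, ], ci_lo = reps[2L, ],
                                      ci_hi = reps[3L, ], covered = covered))
  class(out) <- "replicate_summary"
  out
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("%d replicates, %s, %g%% CI for Q(%d); truth %.4f\n",
              x$n_replicates, x$method, 100 * x$level, x$age, x$truth))
  cat(sprintf("  coverage %.1f%% (MC SE %.1f%%), bias %+.4f, RMSE %.4f\n",
              100 * x$coverage, 100 * x$coverage_se, x$bias, x$rmse))
  invisible(x)
}
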