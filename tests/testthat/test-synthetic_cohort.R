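# Reference cumulative-incidence targets used across the simulation tests:
# male MLH1 carriers, all regions, prospective series (packaged fixture).
male_mlh1_targets <- function() {
  ref <- table1_reference()
  rows <- ref[ref$sex == "male" & ref$gene == "MLH1" &
                ref$region == "All" & ref$source == "PLSD", ]
  rows <- rows[order(rows$age), ]
  list(ages = c(25, rows$age), q = c(0, rows$q_percent / 100))
}

test_that("calibration inverts the recursion exactly (round-trip identity)", {
  zero <- calibrate_hazards(rep(0, 10))
  expect_equal(zero$lambda, rep(0, 9))

  withr_seed(71)
  for (r in seq_len(10L)) {
    q <- c(0, sort(runif(9L, 0, 0.8)))
    model <- calibrate_hazards(q)
    back <- cumulative_recursion(attr(model, "air"), ages = seq(25, 70, 5))
    expect_equal(unname(back), q, tolerance = 1e-12)
    # the continuous-time law implied by lambda reproduces the same targets
    expect_equal(unname(q_from_hazard(model)), q, tolerance = 1e-12)
  }

  # decade-spaced targets (published tables) round-trip at the given ages
  tg <- male_mlh1_targets()
  model <- calibrate_hazards(tg$q, ages = tg$ages)
  back <- cumulative_recursion(attr(model, "air"), ages = tg$ages)
  expect_equal(unname(back), tg$q, tolerance = 1e-12)
})

test_that("decade calibration spreads a constant hazard across each decade", {
  tg <- male_mlh1_targets()
  model <- calibrate_hazards(tg$q, ages = tg$ages)
  # independent algebra: constant hazard on [60,70) from Q(60), Q(70)
  lam_last <- (log(1 - 0.451) - log(1 - 0.519)) / 10
  expect_equal(model$lambda[8L], lam_last, tolerance = 1e-12)
  expect_equal(model$lambda[9L], lam_last, tolerance = 1e-12)
  air_last <- 1 - ((1 - 0.519) / (1 - 0.451))^(1 / 10)
  expect_equal(attr(model, "air")[9L], air_last, tolerance = 1e-12)
})

test_that("calibration rejects invalid targets", {
  expect_error(calibrate_hazards(c(0, 0.3, 0.2, rep(0.4, 7))),
               regexp = "non-decreasing")
  expect_error(calibrate_hazards(c(0, rep(0.5, 8), 1)), regexp = "\\[0, 1\\)")
  expect_error(calibrate_hazards(c(0.1, rep(0.5, 9))), regexp = "Q\\(25\\)")
  expect_error(calibrate_hazards(c(0, 0.5), ages = c(25, 60)),
               regexp = "span age 25 to age 70")
})

test_that("simulation is deterministic given the seed", {
  model <- calibrate_hazards(c(0, sort(runif(9L, 0, 0.5))))
  cfg <- sim_config(n = 200, seed = 99)
  a <- simulate_cohort(model, cfg)
  b <- simulate_cohort(model, cfg)
  expect_identical(as_plain(a), as_plain(b))
  c_ <- simulate_cohort(model, sim_config(n = 200, seed = 100))
  expect_false(identical(a$exit_age, c_$exit_age))
})

test_that("null and saturated hazard models behave as limits", {
  null <- hazard_model(rep(0, 9))
  cohort <- simulate_cohort(null, sim_config(n = 300, seed = 5))
  expect_false(any(cohort$exit_reason == "crc_event"))

  flood <- hazard_model(rep(1e6, 9))
  cohort <- simulate_cohort(flood,
                            sim_config(n = 300, prevalent_fraction = 0,
                                       under25_fraction = 0.1,
                                       followup = list(dist = "fixed",
                                                       value = 10),
                                       seed = 6))
  expect_true(all(cohort$exit_reason == "crc_event"))
  # events strike essentially at the moment hazard begins (entry or age 25)
  expect_true(all(cohort$exit_age - pmax(cohort$entry_age, 25) < 1e-4))
})

test_that("simulator bookkeeping equals the person-time tabulation exactly", {
  model <- calibrate_hazards(male_mlh1_targets()$q,
                             ages = male_mlh1_targets()$ages,
                             gene = "MLH1", sex = "male")
  cohort <- simulate_cohort(model, sim_config(n = 500, seed = 17))
  tab <- tabulate_persontime(cohort, group_by = c("gene", "sex"))[["MLH1.male"]]
  bk <- attr(cohort, "bookkeeping")
  expect_equal(tab$events, bk$true_events)
  expect_equal(tab$person_years, bk$true_person_years, tolerance = 1e-12)
})

test_that("piecewise-exponential sampling matches the exponential law", {
  lam <- 0.05
  model <- hazard_model(c(lam, rep(0, 8)))
  cfg <- sim_config(n = 1e5, entry = list(dist = "fixed", value = 25),
                    followup = list(dist = "fixed", value = 5),
                    prevalent_fraction = 0, under25_fraction = 0, seed = 8)
  cohort <- simulate_cohort(model, cfg)
  p_true <- 1 - exp(-lam * 5)
  p_hat <- mean(cohort$exit_reason == "crc_event")
  se <- sqrt(p_true * (1 - p_true) / 1e5)
  expect_lt(abs(p_hat - p_true), 3 * se)
  # and the within-band event-time law is exponential, not discretized
  t_ev <- cohort$exit_age[cohort$exit_reason == "crc_event"] - 25
  for (t0 in c(1, 2.5, 4)) {
    frac_true <- (1 - exp(-lam * t0)) / p_true
    frac_hat <- mean(t_ev <= t0)
    expect_lt(abs(frac_hat - frac_true),
              3 * sqrt(frac_true * (1 - frac_true) / length(t_ev)))
  }
})

test_that("band hazards are recovered from a simulated cohort", {
  tg <- male_mlh1_targets()
  model <- calibrate_hazards(tg$q, ages = tg$ages, gene = "MLH1", sex = "male")
  cfg <- sim_config(n = 2000, followup = list(dist = "fixed", value = 15),
                    prevalent_fraction = 0, under25_fraction = 0, seed = 9)
  cohort <- simulate_cohort(model, cfg)
  tab <- tabulate_persontime(cohort, group_by = character(0))[[1L]]
  air_hat <- unname(band_air(tab))
  mc_se <- sqrt(pmax(tab$events, 1)) / tab$person_years
  expect_true(all(abs(air_hat - model$lambda) <= 3 * mc_se))
})

test_that("replicate experiments summarize coverage and bias", {
  null <- hazard_model(rep(0, 9))
  cfg <- sim_config(n = 50, prevalent_fraction = 0, seed = 12)
  res <- simulate_many(null, cfg, n_replicates = 20)
  expect_equal(res$truth, 0)
  expect_equal(res$coverage, 1)  # truth 0 always inside [0, upper]
  expect_equal(res$bias, 0)

  tg <- male_mlh1_targets()
  model <- calibrate_hazards(tg$q, ages = tg$ages)
  res <- simulate_many(model, sim_config(n = 300, prevalent_fraction = 0,
                                         under25_fraction = 0,
                                         followup = list(dist = "fixed",
                                                         value = 15),
                                         seed = 13),
                       n_replicates = 60)
  expect_equal(nrow(res$replicates), 60L)
  expect_true(res$coverage > 0.8)
  expect_lt(abs(res$bias), 4 * res$bias_se + 0.01)
})
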