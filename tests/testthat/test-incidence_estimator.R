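test_that("band_air is events over person-years with zero/undefined handling", {
  tab <- persontime_table(c(2, 0, 1, rep(0, 6)), c(500, 300, 6.5, rep(0, 6)))
  air <- band_air(tab)
  expect_equal(air[[1L]], 0.004)
  expect_equal(band_ir(air)[[1L]], 0.02)
  expect_equal(air[[2L]], 0)
  expect_equal(air[[3L]], 1 / 6.5, tolerance = 1e-12)
  expect_equal(unname(air[4:9]), rep(0, 6))

  broken <- persontime_table(c(1, rep(0, 8)), c(10, rep(0, 8)))
  broken$person_years[1L] <- 0  # bypass constructor to hit estimator guard
  expect_error(band_air(broken), regexp = "\\[25,30\\)")
})

test_that("the annual recursion matches its closed-form product exactly", {
  expect_equal(unname(cumulative_recursion(rep(0, 9))), rep(0, 46))

  certain <- cumulative_recursion(c(1, rep(0, 8)))
  expect_equal(certain[["26"]], 1)
  expect_equal(certain[["70"]], 1)

  const <- cumulative_recursion(rep(0.01, 9))
  expect_equal(const[["70"]], 1 - 0.99^45, tolerance = 1e-12)

  withr_seed(21)
  for (r in seq_len(10L)) {
    air <- runif(9L, 0, 0.3)
    expect_equal(unname(cumulative_recursion(air)), product_oracle(air),
                 tolerance = 1e-12)
  }
  expect_error(cumulative_recursion(c(1.2, rep(0, 8))), regexp = "\\[0, 1\\]")
})

test_that("Nelson-Aalen point estimates and zero-event bounds are exact", {
  none <- persontime_table(rep(0L, 9L), rep(300, 9L))
  curve <- nelson_aalen_poisson(none)
  expect_equal(curve$q, rep(0, 10))
  expect_equal(curve$ci_lo, rep(0, 10))
  expect_true(all(curve$ci_hi[-1L] > 0))  # exact Poisson bound, informative
  expect_equal(curve$ci_hi[1L], 0)        # incidence pinned to zero at 25

  single <- persontime_table(c(4L, rep(0L, 8L)), c(1000, rep(0, 8)))
  curve <- nelson_aalen_poisson(single, report_ages = c(25, 30))
  expect_equal(curve$q[2L], 1 - exp(-0.02), tolerance = 1e-12)
  # log-normal interval on H with Var(H) = 25 d / T^2
  se_log <- sqrt(25 * 4 / 1000^2) / 0.02
  z <- qnorm(0.975)
  expect_equal(curve$ci_lo[2L], 1 - exp(-0.02 * exp(-z * se_log)),
               tolerance = 1e-12)
  expect_equal(curve$ci_hi[2L], 1 - exp(-0.02 * exp(z * se_log)),
               tolerance = 1e-12)
})

test_that("incidence curves honour ordering invariants for every method", {
  for (seed in c(31, 32, 33, 34)) {
    tab <- random_persontime(seed)
    for (fn in list(nelson_aalen_poisson, score_ci)) {
      curve <- fn(tab)
      expect_equal(curve$q[1L], 0)
      expect_true(all(diff(curve$q) >= -1e-12))
      expect_true(all(curve$ci_lo <= curve$q + 1e-12))
      expect_true(all(curve$q <= curve$ci_hi + 1e-12))
      expect_true(all(curve$ci_lo >= 0) && all(curve$ci_hi <= 1))
    }
  }
})

test_that("score interval solves the Lagrange-multiplier equation", {
  single <- persontime_table(c(4L, rep(0L, 8L)), c(1000, rep(0, 8)))
  curve <- score_ci(single, report_ages = c(25, 30))
  z <- qnorm(0.975)
  # independent route: numerically invert the score statistic in lambda
  stat <- function(lam) (4 - lam * 1000)^2 / (lam * 1000) - z^2
  lam_lo <- uniroot(stat, c(1e-8, 4e-3), tol = 1e-14)$root
  lam_hi <- uniroot(stat, c(4e-3, 1), tol = 1e-14)$root
  expect_equal(curve$ci_lo[2L], 1 - exp(-lam_lo * 5), tolerance = 1e-8)
  expect_equal(curve$ci_hi[2L], 1 - exp(-lam_hi * 5), tolerance = 1e-8)
  # point estimate matches Nelson-Aalen in the single-band case
  na <- nelson_aalen_poisson(single, report_ages = c(25, 30))
  expect_equal(curve$q[2L], na$q[2L], tolerance = 1e-12)

  zero <- persontime_table(rep(0L, 9L), rep(200, 9L))
  sc <- score_ci(zero)
  expect_equal(sc$ci_lo, rep(0, 10))
  expect_true(all(sc$ci_hi[-1L] > 0))
})

test_that("score and log-normal Poisson intervals agree to first order", {
  big <- persontime_table(c(400L, rep(0L, 8L)), c(20000, rep(0, 8)))
  sc <- score_ci(big, report_ages = 30)
  na <- nelson_aalen_poisson(big, report_ages = 30)
  expect_equal(sc$ci_lo, na$ci_lo, tolerance = 0.01)
  expect_equal(sc$ci_hi, na$ci_hi, tolerance = 0.01)
})

test_that("recursion and Nelson-Aalen discrepancy is hazard-dependent", {
  zero <- persontime_table(rep(0L, 9L), rep(100, 9L))
  expect_equal(attr(compare_methods(zero), "max_abs_diff"), 0)

  # constant annual rate 0.01: close to identical but not equal
  const <- persontime_table(rep(1L, 9L), rep(100, 9L))
  chk <- compare_methods(const)
  expect_true(attr(chk, "max_abs_diff") > 1e-4)
  expect_true(attr(chk, "max_abs_diff") < 0.01)
  expect_false(any(chk$flagged))
  direct <- max(abs((1 - 0.99^(seq(0, 45, 5))) - (1 - exp(-0.01 * seq(0, 45, 5)))))
  expect_equal(attr(chk, "max_abs_diff"), direct, tolerance = 1e-12)

  # a heavy band makes the divergence visible
  heavy <- persontime_table(c(20L, rep(0L, 8L)), c(100, rep(0, 8)))
  chk <- compare_methods(heavy)
  expect_equal(max(abs(chk$q_recursion - chk$q_nelson_aalen)),
               abs((1 - 0.8^5) - (1 - exp(-1))), tolerance = 1e-12)
  expect_true(any(chk$flagged))
})

test_that("weighted means of curves behave like means", {
  a <- nelson_aalen_poisson(random_persontime(41))
  b <- nelson_aalen_poisson(random_persontime(42))
  expect_equal(weighted_mean_curves(list(a), 1)$q, a$q)
  expect_equal(weighted_mean_curves(list(a, a), c(2, 5))$q, a$q)
  mixed <- weighted_mean_curves(list(a, b), c(3, 1))
  expect_equal(mixed$q, 0.75 * a$q + 0.25 * b$q)
  expect_equal(attr(mixed, "ci_pooling"), "approximate")
  # arithmetic check at a single synthetic point
  pa <- a; pa$q[10] <- 0.2; pb <- b; pb$q[10] <- 0.4
  expect_equal(weighted_mean_curves(list(pa, pb), c(3, 1))$q[10], 0.25)
  expect_error(weighted_mean_curves(list(a, b), c(0, 0)), regexp = "weights")
  short <- a[a$age <= 50, ]
  expect_error(weighted_mean_curves(list(a, short), c(1, 1)),
               regexp = "identical age grid")
})
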