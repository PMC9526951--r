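# Builders for in-code fixtures: single records, random valid cohorts and
# random person-time tables under a fixed seed.

make_carrier <- function(carrier_id = "C1", gene = "MLH1", sex = "male",
                         region = "Europe", entry_age = 30, exit_age = 40,
                         exit_reason = "last_observation", prior_crc = FALSE) {
  data.frame(carrier_id = carrier_id, gene = gene, sex = sex, region = region,
             entry_age = entry_age, exit_age = exit_age,
             exit_reason = exit_reason, prior_crc = prior_crc,
             stringsAsFactors = FALSE)
}

make_cohort <- function(...) {
  validate_carriers(do.call(rbind, list(...)))
}

random_cohort <- function(n, seed) {
  withr_seed(seed)
  entry <- runif(n, 20, 68)
  exit <- entry + runif(n, 0, 30)
  data.frame(carrier_id = sprintf("R%04d", seq_len(n)),
             gene = sample(c("MLH1", "MSH2", "MSH6", "PMS2"), n, replace = TRUE),
             sex = sample(c("male", "female"), n, replace = TRUE),
             region = sample(c("Europe", "Australasia"), n, replace = TRUE),
             entry_age = entry, exit_age = exit,
             exit_reason = sample(c("crc_event", "death", "last_observation"),
                                  n, replace = TRUE, prob = c(0.2, 0.2, 0.6)),
             prior_crc = runif(n) < 0.1,
             stringsAsFactors = FALSE) |> validate_carriers()
}

random_persontime <- function(seed, max_n = 50L) {
  withr_seed(seed)
  n_j <- sample.int(max_n, 9L, replace = TRUE) + 1L
  d_j <- vapply(n_j, function(n) sample.int(n, 1L) - 1L, integer(1L))
  persontime_table(d_j, 5 * n_j)
}

# local seed without touching the suite's RNG stream permanently
withr_seed <- function(seed) {
  set.seed(seed)
  invisible(seed)
}

# minimal curve whose age-70 cell carries prescribed values
new_curve_for_render <- function(q70, lo, hi, gene = "MLH1", sex = "male") {
  ages <- seq(25, 70, 5)
  q <- seq(0, q70, length.out = length(ages))
  lynchrisk:::new_incidence_curve(ages, q, pmax(q - 0.05, 0),
                                  pmin(q + 0.05, 1), air = NULL,
                                  method = "synthetic",
                                  stratum = c(gene = gene, sex = sex,
                                              region = "All")) |>
    (function(cv) {
      cv$q[length(ages)] <- q70
      cv$ci_lo[length(ages)] <- lo
      cv$ci_hi[length(ages)] <- hi
      cv
    })()
}

# strip classes/attributes so round-trip comparisons see only the data
as_plain <- function(df) {
  df <- as.data.frame(df)
  attributes(df) <- attributes(df)[c("names", "class", "row.names")]
  class(df) <- "data.frame"
  rownames(df) <- NULL
  df
}

# independent closed-form cumulative incidence: product over elapsed years
product_oracle <- function(air, ages = 25:70) {
  vapply(ages, function(a) {
    if (a <= 25) return(0)
    yrs <- pmin(pmax(a - band_starts(), 0), 5)
    1 - prod((1 - air)^yrs)
  }, numeric(1L))
}
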