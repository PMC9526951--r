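Package: lynchrisk
Title: Prospective Cumulative Colorectal Cancer Incidence in Lynch Syndrome Cohorts
Version: 0.1.0
Authors@R:
    person("PLSD", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Person-time accounting and penetrance estimation for prospectively
    followed carriers of pathogenic mismatch-repair gene variants (Lynch
    syndrome). Converts carrier-level follow-up records into events and
    person-years on five-year age bands under prospective inclusion, age-25
    left truncation, prevalent-case exclusion and right censoring at first
    event, death or last observation; estimates annual incidence rates and
    cumulative colorectal cancer incidence to age 70 by an annual-recursion
    formula, by Nelson-Aalen with Poisson-based confidence intervals, and by a
    score (Lagrange-multiplier) interval; classifies differences between two
    incidence series by confidence-interval overlap rules; and simulates
    synthetic carrier cohorts from piecewise-constant hazards calibratable to
    published cumulative incidences, so that every estimator is testable by
    parameter recovery and coverage experiments without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
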