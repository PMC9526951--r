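# lynchrisk

Person-time accounting and penetrance estimation for prospectively followed
carriers of pathogenic mismatch-repair gene variants (*MLH1*, *MSH2*,
*MSH6*, *PMS2* — Lynch syndrome).

Prospective Lynch-syndrome registries follow confirmed carriers from their
first planned surveillance colonoscopy and record when each carrier exits
observation (incident colorectal cancer, death, or last contact). Estimating
age-specific cancer risk from such data requires careful person-time
bookkeeping: carriers whose cancer occurred before or at inclusion are
prevalent cases and must be excluded, no risk time accrues before inclusion
nor before age 25, and observation is right-censored at the first of event,
death or last contact. `lynchrisk` implements that pipeline end to end, for
epidemiologists and registry analysts:

* **Person-time engine** — validated carrier records in, events `d_j` and
  person-years `T_j` on the nine five-year age bands `[25,30) … [65,70)`
  out, per gene × sex × region stratum.
* **Incidence estimators** — annual incidence rates `AIR_j = d_j / T_j`,
  band risks `IR_j = min(1, 5 AIR_j)`, and cumulative incidence from
  `Q(25) = 0` by the annual recursion
  `Q(a) = Q(a−1) + [1 − Q(a−1)]·AIR(a)` and by Nelson–Aalen
  `Q(a) = 1 − exp(−Σ_j y_j(a)·AIR_j)` with Poisson-based 95% confidence
  intervals (log-normal on the cumulative hazard, exact Poisson bound when
  no events; a score/Lagrange-multiplier interval is also provided).
* **Series comparison** — the three-way CI-overlap rule (disjoint intervals
  = significant; either mean inside the other interval = not significant;
  anything else = inconclusive), with the published prospective (PLSD) and
  retrospective (IMRC) percent cumulative incidences shipped as a plain-CSV
  fixture for reference comparisons.
* **Synthetic cohorts** — piecewise-exponential carrier simulation from
  hazards calibrated to published cumulative incidences, with exact
  bookkeeping, so parameter recovery and interval coverage are testable
  without patient-level data (which are not public).
* **Pipeline & CLI** — `run_pipeline()` and the `inst/cli/lynchrisk` script
  (`tabulate`, `estimate`, `simulate`, `calibrate`, `compare`, `report`)
  tie everything together with JSON configs and CSV/text outputs.

## Worked example

Calibrate a hazard model to the published male *MLH1* prospective cumulative
incidences, simulate a surveillance cohort, tabulate it and estimate risk:

```r
library(lynchrisk)

ref  <- table1_reference()
rows <- ref[ref$sex == "male" & ref$gene == "MLH1" &
            ref$region == "All" & ref$source == "PLSD", ]
rows <- rows[order(rows$age), ]
model <- calibrate_hazards(c(0, rows$q_percent / 100), ages = c(25, rows$age),
                           gene = "MLH1", sex = "male")

cohort <- simulate_cohort(model, sim_config(n = 2000,
                          followup = list(dist = "fixed", value = 15),
                          seed = 2026))
summarize_cohort(cohort)
#> Prospective cohort: 1804 carriers, 23177.1 person-years, 415 CRC events
#> Mean follow-up: 12.8 years
```

1,804 of the 2,000 simulated carriers contribute person-time (the rest are
prevalent cases or never reach age 25 under observation). Tabulate and
estimate:

```r
tab   <- tabulate_persontime(cohort, group_by = c("gene", "sex"))[["MLH1.male"]]
curve <- nelson_aalen_poisson(tab)
render_table1(list(curve))
#>    sex gene region        age_30          age_40           age_50           age_60           age_70
#> 1 male MLH1    All 2.3 (1.0-5.4) 12.6 (9.8-16.0) 29.9 (26.5-33.6) 44.3 (40.9-47.9) 52.3 (48.8-55.9)
```

Estimated cumulative incidence by age 70 is 52.3% (95% CI 48.8–55.9),
recovering the 51.9% the model was calibrated to. Compare against the
retrospective reference series by the CI-overlap rule:

```r
imrc <- reference_curves("IMRC", "All")
classify_curves(curve, imrc[["MLH1.male"]], 70, labels = c("simulated", "IMRC"))
#>   age classification significant direction     q_a     lo_a      hi_a q_b lo_b hi_b
#> 1  70   disjoint_cis        TRUE simulated 0.52284 0.487845 0.5587594 0.4 0.34 0.47
```

The simulated prospective series is significantly higher than the
retrospective 40% (34–47): the intervals are disjoint.

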