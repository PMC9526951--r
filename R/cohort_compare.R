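# CI-overlap classification of two incidence series, and the packaged
# published reference values used as comparison fixtures.

#' Classify the difference between two incidence curves at one age
#'
#' Three-way interval-overlap rule: `disjoint_cis` when the two 95% (or other
#' level) intervals do not overlap — reported as a significant difference;
#' `mean_inside_other_ci` when either point estimate lies inside the other
#' curve's interval — reported as no significant difference; `intermediate`
#' when the intervals overlap but neither mean is covered — an inconclusive
#' overlap that is reported explicitly rather than forced into either class.
#'
#' @param curve_a,curve_b objects with columns `age`, `q`, `ci_lo`, `ci_hi`
#'   (e.g. `incidence_curve`s or rows of [reference_curves()]).
#' @param age report age at which to classify; both curves must carry
#'   non-missing interval bounds there.
#' @param labels length-2 character labels for the two series.
#' @return One-row data frame: `age`, `classification`, `significant`
#'   (`TRUE`/`FALSE`/`NA` for the three classes), `direction` (label of the
#'   higher-mean curve, `"tie"` on equality), and the two means with their
#'   interval endpoints.
#' @export
classify_curves <- function(curve_a, curve_b, age, labels = c("A", "B")) {
  a <- curve_at(curve_a, age, labels[1L])
  b <- curve_at(curve_b, age, labels[2L])
  disjoint <- a$lo > b$hi || b$lo > a$hi
  mean_inside <- (a$q >= b$lo && a$q <= b$hi) || (b$q >= a$lo && b$q <= a$hi)
  cls <- if (disjoint) "disjoint_cis"
         else if (mean_inside) "mean_inside_other_ci"
         else "intermediate"
  data.frame(age = age, classification = cls,
             significant = c(disjoint_cis = TRUE,
                             mean_inside_other_ci = FALSE,
                             intermediate = NA)[[cls]],
             direction = if (a$q > b$q) labels[1L]
                         else if (b$q > a$q) labels[2L] else "tie",
             q_a = a$q, lo_a = a$lo, hi_a = a$hi,
             q_b = b$q, lo_b = b$lo, hi_b = b$hi,
             stringsAsFactors = FALSE)
}

curve_at <- function(curve, age, label) {
  i <- which(curve$age == age)
  if (length(i) != 1L) {
    stop(sprintf("curve '%s' has no unique entry at age %s", label, age),
         call. = FALSE)
  }
  out <- list(q = curve$q[i], lo = curve$ci_lo[i], hi = curve$ci_hi[i])
  if (anyNA(unlist(out))) {
    stop(sprintf("curve '%s' is missing a CI bound at age %s", label, age),
         call. = FALSE)
  }
  if (out$lo > out$q || out$q > out$hi) {
    stop(sprintf("curve '%s' violates lo <= q <= hi at age %s", label, age),
         call. = FALSE)
  }
  out
}

#' Compare two incidence series over matching strata
#'
#' Applies [classify_curves()] at every age where both series carry interval
#' bounds, for every stratum present in both sets. Strata present in only
#' one set are skipped with a warning.
#'
#' @param set_a,set_b named lists of curve-like objects (names identify
#'   strata, e.g. `"MLH1.male"`).
#' @param labels length-2 labels for the two series.
#' @param ages optional ages to classify at; default all shared ages with
#'   complete intervals.
#' @return Data frame of class `comparison_result` with one row per stratum
#'   and age; the attribute `"disjoint_at_70"` lists strata classified
#'   `disjoint_cis` at age 70.
#' @export
compare_series <- function(set_a, set_b, labels = c("A", "B"), ages = NULL) {
  common <- intersect(names(set_a), names(set_b))
  only <- c(setdiff(names(set_a), names(set_b)),
            setdiff(names(set_b), names(set_a)))
  if (length(only) > 0L) {
    warning("skipping strata present in one series only: ",
            paste(only, collapse = ", "), call. = FALSE)
  }
  if (length(common) == 0L) stop("no matching strata", call. = FALSE)
  rows <- lapply(common, function(key) {
    a <- set_a[[key]]
    b <- set_b[[key]]
    shared <- intersect(a$age, b$age)
    ok <- vapply(shared, function(ag) {
      ia <- match(ag, a$age); ib <- match(ag, b$age)
      !anyNA(c(a$ci_lo[ia], a$ci_hi[ia], b$ci_lo[ib], b$ci_hi[ib]))
    }, logical(1L))
    use <- if (is.null(ages)) shared[ok] else intersect(ages, shared[ok])
    if (length(use) == 0L) return(NULL)
    res <- do.call(rbind, lapply(use, function(ag) {
      classify_curves(a, b, ag, labels = labels)
    }))
    cbind(stratum = key, res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_result", "data.frame")
  at70 <- out[out$age == 70 & out$classification == "disjoint_cis", "stratum"]
  attr(out, "disjoint_at_70") <- at70
  attr(out, "labels") <- labels
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  lb <- attr(x, "labels")
  cat(sprintf("Comparison of series %s vs %s (%d stratum-age cells)\n",
              lb[1L], lb[2L], nrow(x)))
  print.data.frame(as.data.frame(x), ...)
  dj <- attr(x, "disjoint_at_70")
  if (length(dj) > 0L) {
    cat("Disjoint 95% CIs at age 70:", paste(dj, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Published cumulative-incidence reference values
#'
#' The packaged fixture of percent cumulative CRC incidences (with 95% CI)
#' at ages 25/30/40/50/60/70 by sex, gene and region, for the prospective
#' (PLSD) and retrospective (IMRC) series, as published. Cells printed as
#' "0 (-)" carry `NA` interval bounds.
#'
#' @return Data frame with columns `sex`, `gene`, `region`, `age`, `source`,
#'   `q_percent`, `lo`, `hi` (the latter three on the percent scale).
#' @export
table1_reference <- function() {
  path <- system.file("extdata", "table1_reference.csv",
                      package = "lynchrisk", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Reference values as curve-like objects
#'
#' Extracts one series (source and region) from [table1_reference()] and
#' reshapes it into a named list of curve-like data frames on the fraction
#' scale, keyed `"<gene>.<sex>"`, suitable for [compare_series()] against
#' estimated `incidence_curve`s.
#'
#' @param source `"PLSD"` or `"IMRC"`.
#' @param region `"All"` or `"Europe"`.
#' @param reference the reference table; defaults to the packaged fixture.
#' @return Named list of data frames with columns `age`, `q`, `ci_lo`,
#'   `ci_hi` (fractions in `[0, 1]`).
#' @export
reference_curves <- function(source = c("PLSD", "IMRC"),
                             region = c("All", "Europe"),
                             reference = table1_reference()) {
  source <- match.arg(source)
  region <- match.arg(region)
  sub <- reference[reference$source == source & reference$region == region, ]
  if (nrow(sub) == 0L) stop("no reference rows for that series", call. = FALSE)
  keys <- unique(paste(sub$gene, sub$sex, sep = "."))
  out <- lapply(keys, function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    rows <- sub[sub$gene == parts[1L] & sub$sex == parts[2L], ]
    rows <- rows[order(rows$age), ]
    data.frame(age = rows$age, q = rows$q_percent / 100,
               ci_lo = rows$lo / 100, ci_hi = rows$hi / 100)
  })
  names(out) <- keys
  out
}
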