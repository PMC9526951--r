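# Domain types and plain-text readers/writers for carrier cohorts,
# person-time tables and incidence curves.

MMR_GENES <- c("MLH1", "MSH2", "MSH6", "PMS2")
SEX_LEVELS <- c("male", "female")
EXIT_REASONS <- c("crc_event", "death", "last_observation")
AGE_START <- 25
AGE_CAP <- 70

CARRIER_COLS <- c("carrier_id", "gene", "sex", "region",
                  "entry_age", "exit_age", "exit_reason", "prior_crc")

#' Five-year age-band grid
#'
#' The unique nine-band partition of ages 25 to 70 into half-open five-year
#' bands `[start, start + 5)`. All person-time accounting and incidence
#' estimation in the package is performed on this grid; follow-up before age
#' 25 is left-truncated and follow-up after the 70th birthday is discarded.
#'
#' @return A data frame with columns `start` and `end` (integer years) and
#'   one row per band, from `[25, 30)` to `[65, 70)`.
#' @examples
#' age_bands()
#' @export
age_bands <- function() {
  data.frame(start = seq(25L, 65L, by = 5L), end = seq(30L, 70L, by = 5L))
}

band_starts <- function() seq(25L, 65L, by = 5L)

band_label <- function(start) sprintf("[%d,%d)", start, start + 5L)

## ---- carrier cohort ---------------------------------------------------------

#' Validate carrier records
#'
#' Checks a data frame of carrier follow-up records against the record
#' invariants: `gene` in MLH1/MSH2/MSH6/PMS2, `sex` male/female, `exit_reason`
#' one of crc_event/death/last_observation, `entry_age > 0`,
#' `exit_age >= entry_age`, ages finite numbers, `prior_crc` logical.
#' `region` is a free label. In strict mode any violation aborts with the
#' offending row numbers; otherwise offending rows are dropped with a warning.
#'
#' @param records data frame with the columns of a carrier record
#'   (`carrier_id`, `gene`, `sex`, `region`, `entry_age`, `exit_age`,
#'   `exit_reason`, `prior_crc`).
#' @param strict abort on any invalid row (default) instead of dropping it.
#' @return A validated data frame of class `carrier_cohort`. When rows were
#'   dropped, the attribute `"dropped"` holds a data frame with columns `row`
#'   and `reason`.
#' @export
validate_carriers <- function(records, strict = TRUE) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(CARRIER_COLS, names(records))
  if (length(missing_cols) > 0L) {
    stop("carrier table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[CARRIER_COLS]
  records$carrier_id <- as.character(records$carrier_id)
  records$gene <- as.character(records$gene)
  records$sex <- as.character(records$sex)
  records$region <- as.character(records$region)
  records$exit_reason <- as.character(records$exit_reason)
  entry <- suppressWarnings(as.numeric(records$entry_age))
  exit <- suppressWarnings(as.numeric(records$exit_age))
  prior <- parse_flag(records$prior_crc)

  reasons <- character(nrow(records))
  flag <- function(bad, why) {
    bad <- which(bad & !nzchar(reasons))
    reasons[bad] <<- why
  }
  flag(!records$gene %in% MMR_GENES, "unknown gene")
  flag(!records$sex %in% SEX_LEVELS, "unknown sex")
  flag(!records$exit_reason %in% EXIT_REASONS, "unknown exit_reason")
  flag(is.na(entry) | !is.finite(entry), "unparseable entry_age")
  flag(is.na(exit) | !is.finite(exit), "unparseable exit_age")
  flag(!is.na(entry) & entry <= 0, "entry_age <= 0")
  flag(!is.na(entry) & !is.na(exit) & exit < entry, "exit_age < entry_age")
  flag(is.na(prior), "unparseable prior_crc")

  bad <- which(nzchar(reasons))
  if (length(bad) > 0L && strict) {
    stop("invalid carrier record(s) in row(s) ",
         paste(sprintf("%d (%s)", bad, reasons[bad]), collapse = "; "),
         call. = FALSE)
  }
  records$entry_age <- entry
  records$exit_age <- exit
  records$prior_crc <- prior
  dropped <- data.frame(row = bad, reason = reasons[bad],
                        stringsAsFactors = FALSE)
  if (length(bad) > 0L) {
    warning(sprintf("dropped %d invalid carrier record(s): %s", length(bad),
                    paste(sprintf("row %d (%s)", bad, reasons[bad]),
                          collapse = "; ")),
            call. = FALSE)
    records <- records[-bad, , drop = FALSE]
  }
  rownames(records) <- NULL
  class(records) <- c("carrier_cohort", "data.frame")
  attr(records, "dropped") <- dropped
  records
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read a carrier cohort from CSV
#'
#' Reads one row per prospectively followed carrier. The file must carry a
#' header naming every carrier-record field; rows are validated with
#' [validate_carriers()].
#'
#' @param path path to a UTF-8 CSV file with dot decimal separators.
#' @param strict abort on the first invalid row (default); when `FALSE`,
#'   invalid rows are dropped and reported in a warning.
#' @return A `carrier_cohort` data frame.
#' @export
read_cohort <- function(path, strict = TRUE) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_carriers(raw, strict = strict)
}

#' Write a carrier cohort to CSV
#'
#' @param cohort a `carrier_cohort` (or compatible data frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)[CARRIER_COLS]
  out$entry_age <- num_chr(out$entry_age)
  out$exit_age <- num_chr(out$exit_age)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# full-precision decimal rendering so CSV round-trips are lossless
num_chr <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

## ---- person-time table ------------------------------------------------------

#' Construct a person-time table
#'
#' Events and person-years on the nine five-year age bands for one stratum;
#' the sufficient statistic for all incidence estimation in the package.
#'
#' @param events integer vector of length 9: CRC events per band.
#' @param person_years numeric vector of length 9: observation years per band.
#' @param stratum named character vector with entries `gene`, `sex`, `region`.
#' @return A data frame of class `persontime_table` with columns `band_start`,
#'   `band_end`, `events`, `person_years` and a `"stratum"` attribute.
#' @export
persontime_table <- function(events = rep(0L, 9L),
                             person_years = rep(0, 9L),
                             stratum = c(gene = "All", sex = "All",
                                         region = "All")) {
  events <- as.numeric(events)
  person_years <- as.numeric(person_years)
  if (length(events) != 9L || length(person_years) != 9L) {
    stop("a person-time table has exactly 9 five-year bands", call. = FALSE)
  }
  if (any(events < 0) || any(events != round(events))) {
    stop("event counts must be non-negative integers", call. = FALSE)
  }
  if (any(person_years < 0) || any(!is.finite(person_years))) {
    stop("person-years must be finite and non-negative", call. = FALSE)
  }
  if (any(events > 0 & person_years <= 0)) {
    stop("a band with events must have positive person-years", call. = FALSE)
  }
  stratum <- complete_stratum(stratum)
  out <- data.frame(band_start = band_starts(),
                    band_end = band_starts() + 5L,
                    events = as.integer(events),
                    person_years = person_years)
  class(out) <- c("persontime_table", "data.frame")
  attr(out, "stratum") <- stratum
  out
}

complete_stratum <- function(stratum) {
  full <- c(gene = "All", sex = "All", region = "All")
  stratum <- stratum[!is.na(stratum)]
  full[names(stratum)[names(stratum) %in% names(full)]] <-
    stratum[names(stratum) %in% names(full)]
  full
}

#' @export
print.persontime_table <- function(x, ...) {
  s <- attr(x, "stratum")
  cat(sprintf("Person-time table (gene=%s, sex=%s, region=%s)\n",
              s[["gene"]], s[["sex"]], s[["region"]]))
  cat(sprintf("  %d events over %.1f person-years\n",
              sum(x$events), sum(x$person_years)))
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}

#' Write a person-time table to CSV
#'
#' Columns: `gene`, `sex`, `region`, `band_start`, `events`, `person_years`;
#' nine rows, one per band (an empty stratum writes nine zero rows).
#'
#' @param table a `persontime_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_persontime <- function(table, path) {
  stopifnot(inherits(table, "persontime_table"))
  s <- attr(table, "stratum")
  out <- data.frame(gene = s[["gene"]], sex = s[["sex"]],
                    region = s[["region"]],
                    band_start = table$band_start,
                    events = table$events,
                    person_years = num_chr(table$person_years))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a person-time table written by [write_persontime()]
#'
#' @param path CSV file path.
#' @return A `persontime_table`.
#' @export
read_persontime <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "sex", "region", "band_start", "events", "person_years")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("person-time CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[order(raw$band_start), ]
  if (!identical(as.integer(raw$band_start), band_starts())) {
    stop("person-time CSV must carry exactly the nine bands starting at ",
         "25, 30, ..., 65", call. = FALSE)
  }
  persontime_table(raw$events, raw$person_years,
                   stratum = c(gene = raw$gene[1L], sex = raw$sex[1L],
                               region = raw$region[1L]))
}

## ---- incidence curve --------------------------------------------------------

new_incidence_curve <- function(age, q, ci_lo, ci_hi, air, method,
                                stratum = c(gene = "All", sex = "All",
                                            region = "All"),
                                level = 0.95) {
  stopifnot(length(age) == length(q), length(q) == length(ci_lo),
            length(q) == length(ci_hi))
  out <- data.frame(age = age, q = q, ci_lo = ci_lo, ci_hi = ci_hi)
  class(out) <- c("incidence_curve", "data.frame")
  attr(out, "air") <- air
  attr(out, "ir") <- if (is.null(air)) NULL else pmin(1, air * 5)
  attr(out, "method") <- method
  attr(out, "stratum") <- complete_stratum(stratum)
  attr(out, "level") <- level
  out
}

#' @export
print.incidence_curve <- function(x, ...) {
  s <- attr(x, "stratum")
  cat(sprintf("Cumulative incidence curve [%s] (gene=%s, sex=%s, region=%s, %g%% CI)\n",
              attr(x, "method"), s[["gene"]], s[["sex"]], s[["region"]],
              100 * attr(x, "level")))
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}

#' Write an incidence curve to CSV
#'
#' Columns `age`, `air`, `q`, `ci_lo`, `ci_hi`, `method` plus the stratum
#' labels. The `air` column holds the annual incidence rate of the band
#' starting at `age` (empty for age 70, where no band starts).
#'
#' @param curve an `incidence_curve` as returned by the estimators.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_incidence_curve <- function(curve, path) {
  stopifnot(inherits(curve, "incidence_curve"))
  s <- attr(curve, "stratum")
  air <- attr(curve, "air")
  air_col <- rep(NA_real_, nrow(curve))
  if (!is.null(air)) {
    idx <- match(curve$age, band_starts())
    air_col[!is.na(idx)] <- air[idx[!is.na(idx)]]
  }
  out <- data.frame(gene = s[["gene"]], sex = s[["sex"]],
                    region = s[["region"]], age = curve$age,
                    air = num_chr(air_col), q = num_chr(curve$q),
                    ci_lo = num_chr(curve$ci_lo), ci_hi = num_chr(curve$ci_hi),
                    method = attr(curve, "method"))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an incidence curve written by [write_incidence_curve()]
#'
#' @param path CSV file path.
#' @return An `incidence_curve`.
#' @export
read_incidence_curve <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "q", "ci_lo", "ci_hi", "method")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("incidence-curve CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[order(raw$age), ]
  air <- NULL
  if ("air" %in% names(raw)) {
    idx <- match(band_starts(), raw$age)
    if (!anyNA(idx)) air <- as.numeric(raw$air[idx])
  }
  stratum <- c(gene = "All", sex = "All", region = "All")
  for (k in c("gene", "sex", "region")) {
    if (k %in% names(raw)) stratum[[k]] <- as.character(raw[[k]][1L])
  }
  new_incidence_curve(raw$age, as.numeric(raw$q), as.numeric(raw$ci_lo),
                      as.numeric(raw$ci_hi), air = air,
                      method = raw$method[1L], stratum = stratum)
}
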