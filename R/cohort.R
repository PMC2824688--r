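# Baseline cohorts: the persons entering the simulation at the start year.

#' Construct a baseline cohort
#'
#' The cohort entering the simulation: one row per person with sex, age at the
#' baseline year (35-79) and CHD/CARP history state. All persons are alive at
#' baseline; the simulation removes a person on death or when attained age
#' reaches 80.
#'
#' @param persons Data frame with columns `id`, `sex`, `age`, `state`.
#' @param baseline_year Calendar year the ages refer to (default 2001).
#' @return An object of class `baseline_cohort`: a list with elements
#'   `persons` (the validated data frame) and `baseline_year`.
#' @export
baseline_cohort <- function(persons, baseline_year = 2001L) {
  required <- c("id", "sex", "age", "state")
  missing_cols <- setdiff(required, names(persons))
  if (length(missing_cols) > 0) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  persons <- as.data.frame(persons)[required]
  persons$id <- as.character(persons$id)
  persons$sex <- as.character(persons$sex)
  persons$age <- as.integer(persons$age)
  persons$state <- as.character(persons$state)
  if (anyDuplicated(persons$id)) {
    stop("duplicate person id: ", persons$id[duplicated(persons$id)][1],
         call. = FALSE)
  }
  check_codes(persons$sex, SEXES, "sex")
  check_codes(persons$state, HISTORY_STATES, "state")
  bad_age <- which(is.na(persons$age) | persons$age < AGE_MIN |
                     persons$age >= AGE_CAP)
  if (length(bad_age) > 0) {
    stop(sprintf("person %s has age %s outside the baseline range 35-79",
                 persons$id[bad_age[1]], persons$age[bad_age[1]]), call. = FALSE)
  }
  structure(list(persons = persons, baseline_year = as.integer(baseline_year)),
            class = "baseline_cohort")
}

#' @export
print.baseline_cohort <- function(x, ...) {
  cat(sprintf("Baseline cohort: %d persons at start of %d\n",
              nrow(x$persons), x$baseline_year))
  tab <- table(x$persons$state)
  for (s in HISTORY_STATES) {
    cat(sprintf("  %-13s %d\n", s, if (s %in% names(tab)) tab[[s]] else 0L))
  }
  invisible(x)
}

#' Read a baseline cohort from CSV
#'
#' Expects the header `id,sex,age,state`; duplicate ids, ages outside 35-79
#' and unknown state codes are rejected with the offending row.
#'
#' @param path Path to a CSV file.
#' @param baseline_year Calendar year of the cohort snapshot (default 2001).
#' @return A [baseline_cohort()].
#' @export
read_cohort_csv <- function(path, baseline_year = 2001L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  if (!all(c("id", "sex", "age", "state") %in% names(df))) {
    stop("cohort CSV must have header id,sex,age,state", call. = FALSE)
  }
  baseline_cohort(df, baseline_year = baseline_year)
}

#' Write a baseline cohort to CSV
#'
#' @param cohort A [baseline_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "baseline_cohort"))
  utils::write.csv(cohort$persons, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
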