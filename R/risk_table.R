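# Annual risk tables: one probability per (year, sex, age band, history state,
# event type) cell, the central input of the simulation.

#' Construct an annual risk table
#'
#' An annual risk table stores, for each calendar year, sex, 5-year age band
#' and CHD/CARP history state, the annual probability of each of the five
#' recognised events. The residual mass `1 - sum(five event probabilities)` is
#' the probability of no event that year, so the five probabilities in any
#' (year, stratum) cell must sum to at most 1; tables violating this are
#' reported by [validate_table()] and rejected by the simulation rather than
#' renormalized.
#'
#' @param entries Data frame with columns `year`, `sex`, `age_band`, `state`,
#'   `event`, `probability` — one row per cell.
#' @param years_covered Inclusive year range the table claims to cover
#'   (used by [validate_table()] for completeness checks). Defaults to
#'   `min(year):max(year)`.
#' @return An object of class `risk_table` (a data frame).
#' @seealso [get_risk()], [validate_table()], [read_risk_csv()]
#' @export
risk_table <- function(entries, years_covered = NULL) {
  required <- c("year", "sex", "age_band", "state", "event", "probability")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    stop("risk table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  entries <- as.data.frame(entries)[required]
  entries$year <- as.integer(entries$year)
  for (col in c("sex", "age_band", "state", "event")) {
    entries[[col]] <- as.character(entries[[col]])
  }
  check_codes(entries$sex, SEXES, "sex")
  check_codes(entries$age_band, AGE_BANDS, "age band")
  check_codes(entries$state, HISTORY_STATES, "state")
  check_codes(entries$event, EVENT_TYPES, "event")
  if (!is.numeric(entries$probability) || any(is.na(entries$probability))) {
    stop("probability column must be numeric with no missing values", call. = FALSE)
  }
  key <- cell_key(entries)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate risk-table cell: ", dup, call. = FALSE)
  }
  if (is.null(years_covered)) {
    years_covered <- seq(min(entries$year), max(entries$year))
  }
  structure(entries,
            years_covered = as.integer(years_covered),
            class = c("risk_table", "data.frame"))
}

cell_key <- function(df) {
  paste(df$year, df$sex, df$age_band, df$state, df$event, sep = "|")
}

#' @export
print.risk_table <- function(x, ...) {
  yrs <- attr(x, "years_covered")
  cat(sprintf("Annual risk table: %d cells, years %d-%d\n",
              nrow(x), min(yrs), max(yrs)))
  NextMethod()
}

#' Years covered by a risk table
#' @param table A `risk_table`.
#' @return Integer vector of calendar years the table declares coverage for.
#' @export
years_covered <- function(table) attr(table, "years_covered")

#' Look up an annual event risk
#'
#' Pure lookup: maps the single-year `age` to its 5-year band and returns the
#' stored probability for that cell. No interpolation is performed.
#'
#' @param table A [risk_table()].
#' @param year Calendar year (must be within `years_covered(table)`).
#' @param sex `"male"` or `"female"`.
#' @param age Attained age in whole years, 35-79.
#' @param state History state code (see [history_states()]).
#' @param event Event type code (see [event_types()]).
#' @return The stored probability (scalar).
#' @export
#' @examples
#' tab <- risk_table(data.frame(year = 2001, sex = "male", age_band = "55-59",
#'                              state = "NO_HISTORY", event = "PCI",
#'                              probability = 0.004))
#' get_risk(tab, 2001, "male", 57, "NO_HISTORY", "PCI")
get_risk <- function(table, year, sex, age, state, event) {
  stopifnot(inherits(table, "risk_table"))
  if (age < AGE_MIN || age >= AGE_CAP) {
    stop(sprintf("age %d outside the supported range 35-79", as.integer(age)),
         call. = FALSE)
  }
  if (!year %in% years_covered(table)) {
    stop(sprintf("incomplete risk table: year %d not covered", as.integer(year)),
         call. = FALSE)
  }
  check_codes(sex, SEXES, "sex")
  check_codes(state, HISTORY_STATES, "state")
  check_codes(event, EVENT_TYPES, "event")
  band <- age_to_band(age)
  hit <- table$year == year & table$sex == sex & table$age_band == band &
    table$state == state & table$event == event
  if (!any(hit)) {
    stop(sprintf("incomplete risk table: missing cell (%d, %s, %s, %s, %s)",
                 as.integer(year), sex, band, state, event), call. = FALSE)
  }
  table$probability[which(hit)[1]]
}

#' Validate an annual risk table
#'
#' Checks every invariant of the format and returns the violations as a data
#' frame rather than raising: probabilities outside `[0, 1]`, (year, stratum)
#' cells whose five event probabilities sum above 1 (leaving no room for the
#' "no event" residual), and cells missing from the full
#' year x sex x band x state x event grid over the declared year range.
#'
#' @param table A [risk_table()].
#' @return Data frame with columns `type` (one of `"probability out of range"`,
#'   `"competing-risk sum exceeds 1"`, `"missing cell"`), `year`, `sex`,
#'   `age_band`, `state`, `event` (`NA` for stratum-level violations) and
#'   `detail`. Zero rows when the table is valid.
#' @export
validate_table <- function(table) {
  stopifnot(inherits(table, "risk_table"))
  violations <- list()

  oob <- table$probability < 0 | table$probability > 1
  if (any(oob)) {
    bad <- table[oob, , drop = FALSE]
    violations[[length(violations) + 1]] <- data.frame(
      type = "probability out of range",
      bad[c("year", "sex", "age_band", "state", "event")],
      detail = sprintf("probability %g", bad$probability)
    )
  }

  ok <- table[!oob, , drop = FALSE]
  if (nrow(ok) > 0) {
    grp <- paste(ok$year, ok$sex, ok$age_band, ok$state, sep = "|")
    sums <- tapply(ok$probability, grp, sum)
    over <- sums[sums > 1 + 1e-12]
    if (length(over) > 0) {
      parts <- strsplit(names(over), "|", fixed = TRUE)
      violations[[length(violations) + 1]] <- data.frame(
        type = "competing-risk sum exceeds 1",
        year = as.integer(vapply(parts, `[`, "", 1)),
        sex = vapply(parts, `[`, "", 2),
        age_band = vapply(parts, `[`, "", 3),
        state = vapply(parts, `[`, "", 4),
        event = NA_character_,
        detail = sprintf("sum %g", as.numeric(over))
      )
    }
  }

  grid <- expand.grid(year = years_covered(table), sex = SEXES,
                      age_band = AGE_BANDS, state = HISTORY_STATES,
                      event = EVENT_TYPES, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  absent <- !(cell_key(grid) %in% cell_key(table))
  if (any(absent)) {
    miss <- grid[absent, , drop = FALSE]
    violations[[length(violations) + 1]] <- data.frame(
      type = "missing cell",
      miss[c("year", "sex", "age_band", "state", "event")],
      detail = "no entry for this cell"
    )
  }

  if (length(violations) == 0) {
    return(data.frame(type = character(), year = integer(), sex = character(),
                      age_band = character(), state = character(),
                      event = character(), detail = character()))
  }
  out <- do.call(rbind, violations)
  rownames(out) <- NULL
  out
}

# Dense 5-d lookup array [year, sex, band, state, event] used by the engine and
# the expectation oracle; NA marks missing cells so access can fail loudly.
risk_array <- function(table, years = years_covered(table)) {
  arr <- array(NA_real_,
               dim = c(length(years), length(SEXES), length(AGE_BANDS),
                       length(HISTORY_STATES), length(EVENT_TYPES)),
               dimnames = list(as.character(years), SEXES, AGE_BANDS,
                               HISTORY_STATES, EVENT_TYPES))
  sel <- table$year %in% years
  sub <- table[sel, , drop = FALSE]
  idx <- cbind(match(sub$year, years),
               match(sub$sex, SEXES),
               match(sub$age_band, AGE_BANDS),
               match(sub$state, HISTORY_STATES),
               match(sub$event, EVENT_TYPES))
  arr[idx] <- sub$probability
  arr
}

#' Read an annual risk table from CSV
#'
#' Expects the header `year,sex,age_band,state,event,probability` with one row
#' per cell; age bands written `"35-39"` style, states and events as the codes
#' in [history_states()] / [event_types()]. Duplicate cells and unknown codes
#' are rejected with the offending row number.
#'
#' @param path Path to a CSV file.
#' @return A [risk_table()].
#' @export
read_risk_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("year", "sex", "age_band", "state", "event", "probability")
  if (!all(required %in% names(df))) {
    stop("risk CSV must have header year,sex,age_band,state,event,probability",
         call. = FALSE)
  }
  key <- cell_key(df)
  if (anyDuplicated(key)) {
    row <- which(duplicated(key))[1]
    stop(sprintf("duplicate risk-table cell at row %d: %s", row, key[row]),
         call. = FALSE)
  }
  for (col in c("sex", "age_band", "state", "event")) {
    valid <- switch(col, sex = SEXES, age_band = AGE_BANDS,
                    state = HISTORY_STATES, event = EVENT_TYPES)
    bad <- which(!df[[col]] %in% valid)
    if (length(bad) > 0) {
      stop(sprintf("unknown %s code %s at row %d", col, df[[col]][bad[1]], bad[1]),
           call. = FALSE)
    }
  }
  if (any(is.na(df$probability))) {
    stop(sprintf("malformed probability at row %d", which(is.na(df$probability))[1]),
         call. = FALSE)
  }
  risk_table(df)
}

#' Write an annual risk table to CSV
#'
#' Inverse of [read_risk_csv()]; `read_risk_csv(write_risk_csv(t, path))`
#' reproduces `t`.
#'
#' @param table A [risk_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_risk_csv <- function(table, path) {
  stopifnot(inherits(table, "risk_table"))
  out <- as.data.frame(table)
  # 17 significant digits: doubles survive the text round trip bit-exactly
  out$probability <- sprintf("%.17g", out$probability)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
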