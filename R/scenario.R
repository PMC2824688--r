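# Declarative scenario modifications of projected risk trajectories, and the
# five built-in incidence scenarios.

#' Define one scenario modification
#'
#' A modification targets a subset of risk-table cells (by event, history
#' state and optionally sex / age band) and either holds the projected
#' trajectory flat at the fitted reference-year level (`"level_off"`) or
#' multiplies it by a factor (`"scale"`).
#'
#' @param events Character vector of event codes to modify.
#' @param states History states to modify (default `"NO_HISTORY"`, the
#'   incident-CHD stratum all built-in scenarios act on).
#' @param kind `"level_off"` or `"scale"`.
#' @param factor Positive multiplier, required for `kind = "scale"` and
#'   ignored for `"level_off"`.
#' @param sexes,age_bands Optional additional filters (default: all).
#' @return An object of class `modification`.
#' @export
#' @examples
#' modification("CHD_ADMISSION_NO_CARP", kind = "scale", factor = 1.2)
modification <- function(events, states = "NO_HISTORY",
                         kind = c("level_off", "scale"), factor = NULL,
                         sexes = NULL, age_bands = NULL) {
  kind <- match.arg(kind)
  check_codes(events, EVENT_TYPES, "event")
  check_codes(states, HISTORY_STATES, "state")
  if (!is.null(sexes)) check_codes(sexes, SEXES, "sex")
  if (!is.null(age_bands)) check_codes(age_bands, AGE_BANDS, "age band")
  if (kind == "scale") {
    if (is.null(factor) || !is.numeric(factor) || length(factor) != 1 ||
        factor <= 0) {
      stop("kind = \"scale\" requires a single positive factor", call. = FALSE)
    }
  } else {
    factor <- NULL
  }
  structure(list(events = events, states = states, kind = kind,
                 factor = factor, sexes = sexes, age_bands = age_bands),
            class = "modification")
}

#' Define a scenario
#'
#' A scenario is a named, ordered list of [modification()]s applied to the
#' projected risk table. An empty modification list is the Base scenario
#' (pure trend extrapolation).
#'
#' @param name Scenario label.
#' @param modifications List of [modification()] objects (possibly empty).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, modifications = list()) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!all(vapply(modifications, inherits, TRUE, "modification"))) {
    stop("modifications must be a list of modification() objects", call. = FALSE)
  }
  structure(list(name = name, modifications = modifications),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario \"%s\": %d modification(s)\n", x$name,
              length(x$modifications)))
  for (m in x$modifications) {
    cat(sprintf("  %s %s on %s in state(s) %s\n", m$kind,
                if (is.null(m$factor)) "" else sprintf("x%.3g", m$factor),
                paste(m$events, collapse = "+"),
                paste(m$states, collapse = "+")))
  }
  invisible(x)
}

#' The five built-in incidence scenarios
#'
#' * `base` — all fitted 1998-2000 trends continue unchanged through the
#'   projection horizon (no modifications).
#' * `incidence1` — the CHD-admission risk for persons with no CHD history
#'   levels off at its fitted reference-year value; all other trends continue.
#' * `incidence2` / `incidence3` — the same risk is increased by 10% / 20%
#'   over its extrapolated trajectory.
#' * `incidence4` — CHD-admission risk +20%, PCI risk +5%, and both the CABG
#'   and CHD-death risks level off, all for the no-history state, while other
#'   trends continue.
#'
#' @return Named list of five [scenario_spec()] objects.
#' @export
builtin_scenarios <- function() {
  adm <- "CHD_ADMISSION_NO_CARP"
  list(
    base = scenario_spec("base"),
    incidence1 = scenario_spec("incidence1", list(
      modification(adm, kind = "level_off"))),
    incidence2 = scenario_spec("incidence2", list(
      modification(adm, kind = "scale", factor = 1.10))),
    incidence3 = scenario_spec("incidence3", list(
      modification(adm, kind = "scale", factor = 1.20))),
    incidence4 = scenario_spec("incidence4", list(
      modification(adm, kind = "scale", factor = 1.20),
      modification("PCI", kind = "scale", factor = 1.05),
      modification("CABG", kind = "level_off"),
      modification("CHD_DEATH", kind = "level_off")))
  )
}

#' Apply a scenario to a projected risk table
#'
#' Modifications are applied in order to the targeted cells:
#' * `level_off` replaces every projected year's value with the cell's fitted
#'   reference-year level from `trends` (optionally the raw observed value,
#'   see `level_off_source`), held flat across the horizon;
#' * `scale` multiplies every projected year's value by `factor`, then clamps
#'   to `[0, 1]`.
#'
#' Untargeted cells are returned bit-identical. If any post-modification
#' (year, stratum) event-probability sum exceeds 1, the call fails.
#'
#' @param projected A [risk_table()] from [project_risks()].
#' @param trends The `trend_table` the projection was built from.
#' @param spec A [scenario_spec()].
#' @param level_off_source `"fitted"` (default: the least-squares value at the
#'   reference year) or `"observed"` (the raw observation, supplied via
#'   `observed`).
#' @param observed A [risk_table()] containing the reference-year observations;
#'   required when `level_off_source = "observed"`.
#' @return A modified [risk_table()] over the same cells and years.
#' @export
apply_scenario <- function(projected, trends, spec,
                           level_off_source = c("fitted", "observed"),
                           observed = NULL) {
  stopifnot(inherits(projected, "risk_table"), inherits(spec, "scenario_spec"))
  level_off_source <- match.arg(level_off_source)
  if (level_off_source == "observed" && is.null(observed)) {
    stop("level_off_source = \"observed\" requires the observed risk table",
         call. = FALSE)
  }
  out <- projected
  for (m in spec$modifications) {
    rows <- out$event %in% m$events & out$state %in% m$states
    if (!is.null(m$sexes)) rows <- rows & out$sex %in% m$sexes
    if (!is.null(m$age_bands)) rows <- rows & out$age_band %in% m$age_bands
    if (!any(rows)) next
    if (m$kind == "scale") {
      out$probability[rows] <- pmin(pmax(out$probability[rows] * m$factor, 0), 1)
    } else {
      out$probability[rows] <- level_off_values(out[rows, , drop = FALSE],
                                                trends, level_off_source,
                                                observed)
    }
  }
  check_projection_sums(out)
  attr(out, "scenario") <- spec$name
  out
}

level_off_values <- function(rows, trends, source, observed) {
  key <- paste(rows$sex, rows$age_band, rows$state, rows$event, sep = "|")
  if (source == "fitted") {
    stopifnot(inherits(trends, "data.frame"))
    tkey <- paste(trends$sex, trends$age_band, trends$state, trends$event,
                  sep = "|")
    idx <- match(key, tkey)
    if (any(is.na(idx))) {
      stop("no fitted trend for cell ", gsub("\\|", ", ", key[is.na(idx)][1]),
           call. = FALSE)
    }
    trends$level[idx]
  } else {
    ref <- max(years_covered(observed))
    obs <- observed[observed$year == ref, , drop = FALSE]
    okey <- paste(obs$sex, obs$age_band, obs$state, obs$event, sep = "|")
    idx <- match(key, okey)
    if (any(is.na(idx))) {
      stop("no observed reference-year value for cell ",
           gsub("\\|", ", ", key[is.na(idx)][1]), call. = FALSE)
    }
    obs$probability[idx]
  }
}

#' Write scenarios to JSON
#'
#' Serializes one or more [scenario_spec()]s as a JSON array of
#' `{"name": ..., "modifications": [{"events": [...], "states": [...],
#' "kind": "scale", "factor": 1.2}, ...]}` objects.
#'
#' @param scenarios A [scenario_spec()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_json <- function(scenarios, path) {
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  payload <- lapply(scenarios, function(s) {
    list(name = s$name, modifications = lapply(s$modifications, function(m) {
      out <- list(events = I(m$events), states = I(m$states), kind = m$kind)
      if (!is.null(m$factor)) out$factor <- m$factor
      if (!is.null(m$sexes)) out$sexes <- I(m$sexes)
      if (!is.null(m$age_bands)) out$age_bands <- I(m$age_bands)
      out
    }))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read scenarios from JSON
#'
#' @param path Path to a JSON file written by [write_scenario_json()] (or
#'   hand-authored in the same shape).
#' @return A named list of [scenario_spec()] objects.
#' @export
read_scenario_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(payload, function(s) {
    mods <- lapply(s$modifications, function(m) {
      modification(events = unlist(m$events),
                   states = if (is.null(m$states)) "NO_HISTORY" else unlist(m$states),
                   kind = m$kind,
                   factor = m$factor,
                   sexes = if (is.null(m$sexes)) NULL else unlist(m$sexes),
                   age_bands = if (is.null(m$age_bands)) NULL else unlist(m$age_bands))
    })
    scenario_spec(s$name, mods)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
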