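# Scenario orchestration and the procedure-totals comparison table
# (total CABGs and PCIs over the horizon per scenario, percent change vs Base).

#' Percent change of a scenario total against the Base total
#'
#' `100 * (scenario_total - base_total) / base_total`, computed from the
#' unrounded totals. Display rounding to two decimals happens only in
#' [render_table()].
#'
#' @param base_total Base-scenario total (must be positive).
#' @param scenario_total Scenario total.
#' @return Percent change (real, unrounded).
#' @export
#' @examples
#' percent_change(10084, 12621) # 25.16 to 2 dp
percent_change <- function(base_total, scenario_total) {
  if (!is.numeric(base_total) || any(base_total <= 0)) {
    stop("base_total must be positive", call. = FALSE)
  }
  100 * (scenario_total - base_total) / base_total
}

#' Project, modify and simulate a set of scenarios
#'
#' For each scenario: extrapolates the fitted trends over the horizon
#' ([project_risks()]), applies the scenario's modifications
#' ([apply_scenario()]), then either runs the stochastic engine
#' ([run_replicates()]) or the deterministic expectation oracle
#' ([expected_counts()]). All scenarios share the cohort and the master seed,
#' so stochastic contrasts use common random numbers: a scenario that leaves
#' every risk unchanged reproduces the Base result bit-for-bit.
#'
#' @param cohort A [baseline_cohort()].
#' @param trends A `trend_table` from [fit_trends()].
#' @param scenarios List of [scenario_spec()]s. A Base scenario (empty
#'   modification list) is prepended if none is present; duplicate names are
#'   an error.
#' @param start_year,end_year Projection/simulation horizon (defaults
#'   2001-2010).
#' @param n_replicates Replicates per scenario in `"simulate"` mode
#'   (default 100).
#' @param master_seed Master seed shared by all scenarios (common random
#'   numbers). Use distinct seeds per scenario only by calling
#'   [run_replicates()] directly.
#' @param mode `"simulate"` (stochastic engine) or `"expected"`
#'   (deterministic expectation).
#' @param floor,cap Clamps passed to [project_risks()].
#' @return An object of class `scenario_comparison`: list with `comparison`
#'   (data frame `scenario`, `event`, `total`, `pct_change_vs_base` for CABG
#'   and PCI), `series` (per-year `scenario`, `year`, `event`, `mean_count`
#'   for CABG and PCI), `results` (per-scenario engine/oracle outputs),
#'   `mode`, `master_seed`.
#' @export
run_scenarios <- function(cohort, trends, scenarios = builtin_scenarios(),
                          start_year = 2001L, end_year = 2010L,
                          n_replicates = 100L, master_seed = 1L,
                          mode = c("simulate", "expected"),
                          floor = 0, cap = 1) {
  mode <- match.arg(mode)
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  nm <- vapply(scenarios, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("duplicate scenario name: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  is_base <- vapply(scenarios, function(s) length(s$modifications) == 0, TRUE)
  if (!any(is_base)) {
    scenarios <- c(list(scenario_spec("base")), scenarios)
    is_base <- c(TRUE, is_base)
    nm <- c("base", nm)
  }
  base_name <- nm[which(is_base)[1]]

  years <- seq(as.integer(start_year), as.integer(end_year))
  projected <- project_risks(trends, years = years, floor = floor, cap = cap)

  results <- list()
  series_list <- list()
  totals <- list()
  for (i in seq_along(scenarios)) {
    spec <- scenarios[[i]]
    tab <- apply_scenario(projected, trends, spec)
    if (mode == "simulate") {
      res <- run_replicates(cohort, tab, start_year, end_year,
                            n_replicates = n_replicates,
                            master_seed = master_seed)
      per_year <- res$averaged
      names(per_year)[names(per_year) == "mean_count"] <- "mean_count"
    } else {
      exp_ <- expected_counts(cohort, tab, start_year, end_year)
      res <- exp_
      per_year <- data.frame(year = exp_$year, event = exp_$event,
                             mean_count = exp_$expected)
    }
    results[[spec$name]] <- res
    carp <- per_year[per_year$event %in% CARP_EVENTS, , drop = FALSE]
    carp <- data.frame(scenario = spec$name, carp, row.names = NULL)
    series_list[[spec$name]] <- carp
    totals[[spec$name]] <- tapply(carp$mean_count, carp$event, sum)
  }

  base_tot <- totals[[base_name]]
  comparison <- do.call(rbind, lapply(names(totals), function(s) {
    data.frame(scenario = s, event = CARP_EVENTS,
               total = as.numeric(totals[[s]][CARP_EVENTS]),
               pct_change_vs_base = percent_change(
                 as.numeric(base_tot[CARP_EVENTS]),
                 as.numeric(totals[[s]][CARP_EVENTS])))
  }))
  rownames(comparison) <- NULL
  structure(list(comparison = comparison,
                 series = do.call(rbind, c(series_list, make.row.names = FALSE)),
                 results = results, mode = mode, base = base_name,
                 master_seed = as.integer(master_seed),
                 n_replicates = if (mode == "simulate") as.integer(n_replicates) else NA_integer_),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(render_table(x), sep = "\n")
  invisible(x)
}

#' Render the scenario comparison as text and CSV
#'
#' One row per procedure (CABG, PCI) with per-scenario totals and the percent
#' change from the Base scenario, rounded to two decimals for display (the
#' CSV keeps full precision).
#'
#' @param comparison A `scenario_comparison` from [run_scenarios()].
#' @param csv_path Optional path; when given, the tidy comparison
#'   (`scenario`, `event`, `total`, `pct_change_vs_base`) is written there.
#' @return Character vector of display lines, invisibly when printing.
#' @export
render_table <- function(comparison, csv_path = NULL) {
  stopifnot(inherits(comparison, "scenario_comparison"))
  cmp <- comparison$comparison
  if (!is.null(csv_path)) {
    out <- cmp
    out$total <- sprintf("%.17g", out$total)
    out$pct_change_vs_base <- sprintf("%.17g", out$pct_change_vs_base)
    utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  }
  scen <- unique(cmp$scenario)
  header <- sprintf("%-28s %s", "Total event",
                    paste(sprintf("%12s", scen), collapse = " "))
  lines <- header
  for (ev in CARP_EVENTS) {
    row <- cmp[cmp$event == ev, , drop = FALSE]
    tot <- row$total[match(scen, row$scenario)]
    lines <- c(lines, sprintf("%-28s %s", ev,
                              paste(sprintf("%12.0f", tot), collapse = " ")))
    pct <- row$pct_change_vs_base[match(scen, row$scenario)]
    pct_str <- ifelse(scen == comparison$base, sprintf("%12s", "---"),
                      sprintf("%12.2f", round(pct, 2)))
    lines <- c(lines, sprintf("%-28s %s", "  % change from base",
                              paste(pct_str, collapse = " ")))
  }
  lines
}

#' Read a scenario comparison CSV back into a data frame
#'
#' Convenience inverse of the CSV written by [render_table()].
#'
#' @param path CSV path.
#' @return Data frame with `scenario`, `event`, `total`, `pct_change_vs_base`.
#' @export
read_comparison_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
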