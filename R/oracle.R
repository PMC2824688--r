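# Deterministic expectation twin of the stochastic engine: enumerates the
# identical within-year sub-cycle tree and propagates the cohort's state
# distribution, giving exact expected event counts with no Monte Carlo error.

#' Expected event counts under the within-year rule
#'
#' Computes, for every simulated year and event type, the exact expected
#' number of events under the same sub-cycle rule the stochastic engine
#' samples from: for each person-year the full outcome tree (first draw over
#' the five events plus "none", then up to two CARP-only follow-on draws at
#' the updated state's risks) is enumerated and the end-of-year state
#' distribution propagated, with ageing and removal at age 80 exactly as in
#' [simulate_cohort()]. Engine averages converge to these values as the
#' number of replicates grows.
#'
#' @inheritParams simulate_cohort
#' @return Data frame with columns `year`, `event`, `expected`. The
#'   `"mass"` attribute holds end-of-year accounting (`year`, `alive`,
#'   `died`, `aged_out`; the three always sum to the cohort size).
#' @export
expected_counts <- function(cohort, table, start_year = cohort$baseline_year,
                            end_year = 2010L) {
  stopifnot(inherits(cohort, "baseline_cohort"), inherits(table, "risk_table"))
  years <- seq(as.integer(start_year), as.integer(end_year))
  if (!all(years %in% years_covered(table))) {
    stop("risk table does not cover the simulation horizon", call. = FALSE)
  }
  arr <- risk_array(table, years = years)
  n_states <- length(HISTORY_STATES)
  ages <- AGE_MIN:(AGE_CAP - 1L)

  # alive mass by (sex, age, state)
  mass <- array(0, dim = c(2L, length(ages), n_states))
  p <- cohort$persons
  idx <- cbind(match(p$sex, SEXES), match(p$age, ages),
               match(p$state, HISTORY_STATES))
  for (i in seq_len(nrow(idx))) {
    mass[idx[i, 1], idx[i, 2], idx[i, 3]] <- mass[idx[i, 1], idx[i, 2], idx[i, 3]] + 1
  }
  n_total <- nrow(p)
  died_mass <- 0
  aged_out_mass <- 0

  counts <- matrix(0, nrow = length(years), ncol = 5L,
                   dimnames = list(as.character(years), EVENT_TYPES))
  ledger <- data.frame(year = years, alive = NA_real_, died = NA_real_,
                       aged_out = NA_real_)

  for (t in seq_along(years)) {
    # one outcome tree per (sex, band, state); trees are reused across the
    # five single-year ages sharing a band
    trees <- vector("list", 2L * length(AGE_BANDS) * n_states)
    tree_at <- function(s, b, k) {
      pos <- ((s - 1L) * length(AGE_BANDS) + (b - 1L)) * n_states + k
      if (is.null(trees[[pos]])) {
        pfun <- function(state_i) {
          pr <- arr[t, s, b, state_i, ]
          if (anyNA(pr)) {
            stop(sprintf("incomplete risk table: missing cell (%d, %s, %s, %s)",
                         years[t], SEXES[s], AGE_BANDS[b],
                         HISTORY_STATES[state_i]), call. = FALSE)
          }
          if (sum(pr) > 1 + 1e-9) {
            stop(sprintf("competing-risk sum %g exceeds 1 in (%d, %s, %s, %s)",
                         sum(pr), years[t], SEXES[s], AGE_BANDS[b],
                         HISTORY_STATES[state_i]), call. = FALSE)
          }
          pr
        }
        trees[[pos]] <<- subcycle_tree(pfun, k)
      }
      trees[[pos]]
    }

    new_mass <- array(0, dim = dim(mass))
    for (s in 1:2) for (a in seq_along(ages)) for (k in seq_len(n_states)) {
      m <- mass[s, a, k]
      if (m == 0) next
      b <- (ages[a] - AGE_MIN) %/% 5L + 1L
      tr <- tree_at(s, b, k)
      counts[t, ] <- counts[t, ] + m * tr$events
      died_mass <- died_mass + m * tr$p_died
      surv <- m * tr$end_state # length-4 vector over end states
      if (ages[a] + 1L >= AGE_CAP) {
        aged_out_mass <- aged_out_mass + sum(surv)
      } else {
        new_mass[s, a + 1L, ] <- new_mass[s, a + 1L, ] + surv
      }
    }
    mass <- new_mass
    ledger$alive[t] <- sum(mass)
    ledger$died[t] <- died_mass
    ledger$aged_out[t] <- aged_out_mass
  }

  out <- data.frame(year = rep(years, times = 5L),
                    event = rep(EVENT_TYPES, each = length(years)),
                    expected = as.vector(counts))
  attr(out, "mass") <- ledger
  attr(out, "n_total") <- n_total
  out
}

# Exhaustive enumeration of one person-year's sub-cycle outcome tree.
# pfun(state_index) returns the five event probabilities at that state.
# Returns expected event counts (length 5), the end-of-year state
# distribution among survivors (length 4) and the death probability.
subcycle_tree <- function(pfun, state0) {
  events <- numeric(5L)
  end_state <- numeric(length(HISTORY_STATES))
  p_died <- 0

  i_cabg <- match("CABG_HISTORY", HISTORY_STATES)
  i_pci <- match("PCI_NO_CABG", HISTORY_STATES)
  after <- function(st, ev) {
    if (ev == EVT_ADM) {
      if (st == match("NO_HISTORY", HISTORY_STATES)) match("CHD_NO_CARP", HISTORY_STATES) else st
    } else if (ev == EVT_CABG) {
      i_cabg
    } else { # PCI
      if (st == i_cabg) st else i_pci
    }
  }

  # follow-on draws over {CABG, PCI, none} until "none" or two CARPs
  follow <- function(w, st, carps) {
    if (w == 0) return()
    if (carps >= 2L) {
      end_state[st] <<- end_state[st] + w
      return()
    }
    q <- pfun(st)[c(EVT_CABG, EVT_PCI)]
    end_state[st] <<- end_state[st] + w * (1 - sum(q))
    for (d in 1:2) {
      ev <- c(EVT_CABG, EVT_PCI)[d]
      events[ev] <<- events[ev] + w * q[d]
      follow(w * q[d], after(st, ev), carps + 1L)
    }
  }

  p <- pfun(state0)
  end_state[state0] <- end_state[state0] + (1 - sum(p)) # no event
  events[EVT_CHD_DEATH] <- p[EVT_CHD_DEATH]
  events[EVT_NONCHD_DEATH] <- p[EVT_NONCHD_DEATH]
  p_died <- p[EVT_CHD_DEATH] + p[EVT_NONCHD_DEATH]

  events[EVT_ADM] <- p[EVT_ADM]
  follow(p[EVT_ADM], after(state0, EVT_ADM), 0L)
  for (ev in c(EVT_CABG, EVT_PCI)) {
    events[ev] <- events[ev] + p[ev]
    follow(p[ev], after(state0, ev), 1L)
  }

  list(events = events, end_state = end_state, p_died = p_died)
}

#' Write expected counts to disk
#'
#' Same schema as the engine's averaged-counts output (`averaged.csv`:
#' `year`, `event`, `mean_count`) with metadata flagged `mode = "expected"`.
#'
#' @param expected Result of [expected_counts()].
#' @param dir Output directory (created if absent).
#' @param scenario Optional scenario label recorded in the metadata.
#' @return `dir`, invisibly.
#' @export
write_expected_counts <- function(expected, dir, scenario = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- data.frame(year = expected$year, event = expected$event,
                    mean_count = expected$expected)
  utils::write.csv(out, file.path(dir, "averaged.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- list(mode = "expected")
  if (!is.null(scenario)) meta$scenario <- scenario
  jsonlite::write_json(meta, file.path(dir, "metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}
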