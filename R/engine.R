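# Stochastic year-by-year microsimulation of the cohort.
#
# Within-year rule (one cycle): a single categorical draw over the five events
# plus "no event" at the person's current-state risks; death ends the year and
# the person; a CHD admission or a CARP updates the history state immediately
# and permits a follow-on draw over {CABG, PCI, none} at the *updated* state's
# risks; at most two CARPs per year, after which the year ends. Mortality risk
# acts only in the first draw, once per year. Ages increment at year end; a
# person is removed when attained age reaches 80.
#
# RNG layout: each replicate-year draws three uniform vectors u1, u2, u3 over
# ALL cohort members (dead ones included) in a fixed order; person i uses
# u1[i] for the first draw and u2[i]/u3[i] for the follow-on draws whether or
# not they are needed. Uniform consumption therefore never depends on
# outcomes, so two scenarios run under one master seed assign identical
# deviates to identical person-year-stages (exact common random numbers).

EVT_ADM <- 1L; EVT_CABG <- 2L; EVT_PCI <- 3L; EVT_CHD_DEATH <- 4L; EVT_NONCHD_DEATH <- 5L

#' Simulate one person-year
#'
#' Scalar reference implementation of the within-year sub-cycle rule. Takes
#' the (up to) three uniform deviates explicitly so that traces can be
#' hand-checked and compared against the vectorized cohort engine
#' deviate-for-deviate.
#'
#' @param person List or one-row data frame with `id`, `sex`, `age`, `state`.
#' @param year Calendar year to simulate.
#' @param table A [risk_table()] covering `year`.
#' @param u Numeric vector of three uniforms in `[0, 1)`: first draw,
#'   first follow-on, second follow-on. Defaults to fresh `runif(3)`.
#' @return A list (class `year_outcome`) with `id`, `year`, `events`
#'   (character vector, 0-3 entries, death last), `end_state`, `died`,
#'   `aged_out` and `age` (attained age after the year).
#' @export
simulate_person_year <- function(person, year, table, u = stats::runif(3)) {
  stopifnot(length(u) == 3, all(u >= 0 & u <= 1))
  sex <- as.character(person$sex)
  age <- as.integer(person$age)
  state <- as.character(person$state)
  p <- vapply(EVENT_TYPES, function(e) get_risk(table, year, sex, age, state, e),
              numeric(1))
  if (sum(p) > 1 + 1e-9) {
    stop(sprintf("competing-risk sum %g exceeds 1 in (%d, %s, %s, %s)",
                 sum(p), year, sex, age_to_band(age), state), call. = FALSE)
  }
  events <- character(0)
  died <- FALSE
  d1 <- 1L + sum(u[1] >= cumsum(p))
  if (d1 <= 5L) events <- EVENT_TYPES[d1]
  if (d1 %in% c(EVT_CHD_DEATH, EVT_NONCHD_DEATH)) {
    died <- TRUE
  } else if (d1 <= 3L) {
    state <- state_after_event(state, EVENT_TYPES[d1])
    carps <- as.integer(d1 %in% c(EVT_CABG, EVT_PCI))
    for (stage in 2:3) {
      if (carps >= 2L) break
      q <- c(get_risk(table, year, sex, age, state, "CABG"),
             get_risk(table, year, sex, age, state, "PCI"))
      d <- 1L + sum(u[stage] >= cumsum(q))
      if (d == 3L) break
      ev <- CARP_EVENTS[d]
      events <- c(events, ev)
      state <- state_after_event(state, ev)
      carps <- carps + 1L
    }
  }
  aged_out <- FALSE
  if (!died) {
    age <- age + 1L
    aged_out <- age >= AGE_CAP
  }
  structure(list(id = person$id, year = as.integer(year), events = events,
                 end_state = state, died = died, aged_out = aged_out,
                 age = age),
            class = "year_outcome")
}

# Vectorized core: simulates the whole cohort over `years` using the current
# RNG stream. Returns per-year event counts and final person status.
sim_core <- function(sex_i, age, state_i, arr, years) {
  n <- length(age)
  n_years <- length(years)
  counts <- matrix(0, nrow = n_years, ncol = 5L,
                   dimnames = list(as.character(years), EVENT_TYPES))
  # status: 1 active, 2 died (CHD), 3 died (non-CHD), 4 aged out
  status <- rep(1L, n)

  lookup <- function(t, who, st_i, ev) {
    p <- arr[cbind(t, sex_i[who], (age[who] - AGE_MIN) %/% 5L + 1L, st_i, ev)]
    if (anyNA(p)) {
      j <- which(is.na(p))[1]
      stop(sprintf("incomplete risk table: missing cell (%d, %s, %s, %s, %s)",
                   years[t], SEXES[sex_i[who][j]],
                   AGE_BANDS[(age[who][j] - AGE_MIN) %/% 5L + 1L],
                   HISTORY_STATES[st_i[j]], EVENT_TYPES[ev]), call. = FALSE)
    }
    p
  }

  for (t in seq_len(n_years)) {
    u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
    act <- which(status == 1L)
    if (length(act) == 0L) next
    P <- vapply(1:5, function(e) lookup(t, act, state_i[act], e),
                numeric(length(act)))
    P <- matrix(P, ncol = 5L)
    tot <- rowSums(P)
    if (any(tot > 1 + 1e-9)) {
      j <- which(tot > 1 + 1e-9)[1]
      stop(sprintf("competing-risk sum %g exceeds 1 in (%d, %s, %s, %s)",
                   tot[j], years[t], SEXES[sex_i[act][j]],
                   AGE_BANDS[(age[act][j] - AGE_MIN) %/% 5L + 1L],
                   HISTORY_STATES[state_i[act][j]]), call. = FALSE)
    }
    cum <- P
    for (e in 2:5) cum[, e] <- cum[, e - 1L] + P[, e]
    uu <- u1[act]
    d1 <- 1L + (uu >= cum[, 1L]) + (uu >= cum[, 2L]) + (uu >= cum[, 3L]) +
      (uu >= cum[, 4L]) + (uu >= cum[, 5L])
    counts[t, ] <- counts[t, ] + tabulate(d1[d1 <= 5L], nbins = 5L)

    status[act[d1 == EVT_CHD_DEATH]] <- 2L
    status[act[d1 == EVT_NONCHD_DEATH]] <- 3L

    # state updates from the first draw, then up to two CARP-only follow-ons
    first_nonfatal <- d1 <= 3L
    upd <- act[first_nonfatal]
    if (length(upd) > 0L) {
      state_i[upd] <- state_after_idx(state_i[upd], d1[first_nonfatal])
      carps <- as.integer(d1[first_nonfatal] %in% c(EVT_CABG, EVT_PCI))
      for (stage in 1:2) {
        open <- which(carps < 2L)
        if (length(open) == 0L) break
        who <- upd[open]
        q_cabg <- lookup(t, who, state_i[who], EVT_CABG)
        q_pci <- lookup(t, who, state_i[who], EVT_PCI)
        uf <- if (stage == 1L) u2[who] else u3[who]
        d <- 1L + (uf >= q_cabg) + (uf >= q_cabg + q_pci)
        got_cabg <- who[d == 1L]
        got_pci <- who[d == 2L]
        counts[t, EVT_CABG] <- counts[t, EVT_CABG] + length(got_cabg)
        counts[t, EVT_PCI] <- counts[t, EVT_PCI] + length(got_pci)
        state_i[got_cabg] <- match("CABG_HISTORY", HISTORY_STATES)
        pci_upd <- got_pci[state_i[got_pci] != match("CABG_HISTORY", HISTORY_STATES)]
        state_i[pci_upd] <- match("PCI_NO_CABG", HISTORY_STATES)
        # close persons whose draw was "none" or who reached two CARPs
        carps[open[d <= 2L]] <- carps[open[d <= 2L]] + 1L
        carps[open[d == 3L]] <- 2L
      }
    }

    alive <- status == 1L
    age[alive] <- age[alive] + 1L
    status[alive & age >= AGE_CAP] <- 4L
  }
  list(counts = counts, status = status, age = age, state_i = state_i)
}

# index-space twin of state_after_event for the first draw (d1 in 1..3)
state_after_idx <- function(state_i, d1) {
  out <- state_i
  i_no <- match("NO_HISTORY", HISTORY_STATES)
  i_chd <- match("CHD_NO_CARP", HISTORY_STATES)
  i_pci <- match("PCI_NO_CABG", HISTORY_STATES)
  i_cabg <- match("CABG_HISTORY", HISTORY_STATES)
  out[d1 == EVT_ADM & state_i == i_no] <- i_chd
  out[d1 == EVT_CABG] <- i_cabg
  out[d1 == EVT_PCI & state_i != i_cabg] <- i_pci
  out
}

#' Simulate one replicate of the cohort
#'
#' Runs every cohort member independently through [simulate_person_year()]'s
#' rule (vectorized) from `start_year` to `end_year`, until death, age 80, or
#' the end of the horizon.
#'
#' @param cohort A [baseline_cohort()].
#' @param table A [risk_table()] covering `start_year:end_year`.
#' @param start_year,end_year Simulation horizon (defaults: the cohort's
#'   baseline year through 2010).
#' @param seed Integer seed for this replicate.
#' @return A list (class `cohort_replicate`) with `counts` (data frame
#'   `year`, `event`, `count`), `final` (per-person end state and status:
#'   `"alive"`, `"died_chd"`, `"died_nonchd"`, `"aged_out"`), and the horizon.
#' @export
simulate_cohort <- function(cohort, table, start_year = cohort$baseline_year,
                            end_year = 2010L, seed = NULL) {
  stopifnot(inherits(cohort, "baseline_cohort"), inherits(table, "risk_table"))
  years <- seq(as.integer(start_year), as.integer(end_year))
  if (!all(years %in% years_covered(table))) {
    stop("risk table does not cover the simulation horizon", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  arr <- risk_array(table, years = years)
  p <- cohort$persons
  res <- sim_core(match(p$sex, SEXES), p$age, match(p$state, HISTORY_STATES),
                  arr, years)
  counts <- data.frame(year = rep(years, times = 5L),
                       event = rep(EVENT_TYPES, each = length(years)),
                       count = as.vector(res$counts))
  final <- data.frame(id = p$id, sex = p$sex, age = res$age,
                      state = HISTORY_STATES[res$state_i],
                      status = c("alive", "died_chd", "died_nonchd",
                                 "aged_out")[res$status])
  structure(list(counts = counts, final = final, start_year = years[1],
                 end_year = years[length(years)]),
            class = "cohort_replicate")
}

#' Run replicate simulations and average event counts
#'
#' Performs `n_replicates` independent stochastic simulations of the cohort
#' (100 in the published analysis) and averages the per-year event counts.
#' Replicate `r` uses a substream seed drawn deterministically from
#' `master_seed`, so identical inputs and master seed give a bit-identical
#' result, independent of how replicates are scheduled.
#'
#' @inheritParams simulate_cohort
#' @param n_replicates Number of replicate simulations (default 100).
#' @param master_seed Integer master seed.
#' @return An object of class `simulation_result`: list with `counts`
#'   (data frame `replicate`, `year`, `event`, `count`), `averaged`
#'   (`year`, `event`, `mean_count`), `status` (per-replicate counts of
#'   persons `alive`, `died`, `aged_out` at end), `n_replicates`,
#'   `master_seed` and the horizon.
#' @export
run_replicates <- function(cohort, table, start_year = cohort$baseline_year,
                           end_year = 2010L, n_replicates = 100L,
                           master_seed = 1L) {
  stopifnot(n_replicates >= 1)
  seeds <- substream_seeds(master_seed, n_replicates)
  counts_list <- vector("list", n_replicates)
  status <- data.frame(replicate = seq_len(n_replicates), alive = 0L,
                       died = 0L, aged_out = 0L)
  for (r in seq_len(n_replicates)) {
    rep_r <- simulate_cohort(cohort, table, start_year, end_year,
                             seed = seeds[r])
    cc <- rep_r$counts
    cc$replicate <- r
    counts_list[[r]] <- cc
    status$alive[r] <- sum(rep_r$final$status == "alive")
    status$died[r] <- sum(rep_r$final$status %in% c("died_chd", "died_nonchd"))
    status$aged_out[r] <- sum(rep_r$final$status == "aged_out")
  }
  counts <- do.call(rbind, counts_list)
  counts <- counts[c("replicate", "year", "event", "count")]
  key <- paste(counts$year, counts$event, sep = "|")
  mean_count <- tapply(counts$count, key, mean)
  parts <- strsplit(names(mean_count), "|", fixed = TRUE)
  averaged <- data.frame(year = as.integer(vapply(parts, `[`, "", 1)),
                         event = vapply(parts, `[`, "", 2),
                         mean_count = as.numeric(mean_count))
  averaged <- averaged[order(averaged$year, match(averaged$event, EVENT_TYPES)), ]
  rownames(averaged) <- NULL
  structure(list(counts = counts, averaged = averaged, status = status,
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed),
                 start_year = as.integer(start_year),
                 end_year = as.integer(end_year)),
            class = "simulation_result")
}

# Deterministic substream seeds: a fixed-seed draw from the master seed.
substream_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max, n)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Simulation result: %d replicates, %d-%d (master seed %d)\n",
              x$n_replicates, x$start_year, x$end_year, x$master_seed))
  tot <- tapply(x$averaged$mean_count, x$averaged$event, sum)
  for (e in EVENT_TYPES) {
    cat(sprintf("  %-22s total (mean over replicates) %.1f\n", e, tot[[e]]))
  }
  invisible(x)
}

#' Write a simulation result to disk
#'
#' Emits the per-replicate counts (`counts.csv`: replicate, year, event,
#' count), the replicate-averaged counts (`averaged.csv`: year, event,
#' mean_count) and run metadata (`metadata.json`: master seed, replicate
#' count, horizon, mode and scenario label when known).
#'
#' @param result A `simulation_result` from [run_replicates()].
#' @param dir Output directory (created if absent).
#' @param scenario Optional scenario label recorded in the metadata.
#' @return `dir`, invisibly.
#' @export
write_simulation_result <- function(result, dir, scenario = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$counts, file.path(dir, "counts.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$averaged, file.path(dir, "averaged.csv"),
                   row.names = FALSE, quote = FALSE)
  meta <- list(master_seed = result$master_seed,
               n_replicates = result$n_replicates,
               start_year = result$start_year, end_year = result$end_year,
               mode = "simulated")
  if (!is.null(scenario)) meta$scenario <- scenario
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
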