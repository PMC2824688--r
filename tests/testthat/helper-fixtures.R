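# Fixture builders and an independent brute-force expectation oracle, all
# generated in code at test time.

# Full-grid risk table with the same five event probabilities in every
# stratum of every year.
uniform_risk_table <- function(years, probs) {
  stopifnot(length(probs) == 5)
  if (is.null(names(probs))) names(probs) <- event_types()
  grid <- expand.grid(year = as.integer(years), sex = c("male", "female"),
                      age_band = age_bands(), state = history_states(),
                      event = event_types(), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$probability <- as.numeric(probs[grid$event])
  risk_table(grid, years_covered = years)
}

# Full-grid risk table from a cell function f(year, sex, age_band, state,
# event) -> probability (evaluated row-wise).
risk_table_from_fun <- function(years, f) {
  grid <- expand.grid(year = as.integer(years), sex = c("male", "female"),
                      age_band = age_bands(), state = history_states(),
                      event = event_types(), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$probability <- mapply(f, grid$year, grid$sex, grid$age_band,
                             grid$state, grid$event)
  risk_table(grid, years_covered = years)
}

# State-dependent table: probs_by_state is a list state -> named numeric(5).
state_risk_table <- function(years, probs_by_state) {
  risk_table_from_fun(years, function(year, sex, band, state, event) {
    probs_by_state[[state]][[event]]
  })
}

tiny_cohort <- function(ages, states, sexes = "male", baseline_year = 2001) {
  n <- max(length(ages), length(states), length(sexes))
  baseline_cohort(data.frame(id = sprintf("T%02d", seq_len(n)),
                             sex = rep_len(sexes, n),
                             age = rep_len(ages, n),
                             state = rep_len(states, n)),
                  baseline_year = baseline_year)
}

# --- independent brute-force oracle ----------------------------------------
# Exhaustive enumeration over full multi-year outcome paths, written flat
# (explicit loops over every admissible within-year event sequence) so it
# shares no code with carpsim::expected_counts.

bf_step_state <- function(state, event) {
  if (event == "CABG") return("CABG_HISTORY")
  if (event == "PCI") {
    return(if (state == "CABG_HISTORY") "CABG_HISTORY" else "PCI_NO_CABG")
  }
  if (event == "CHD_ADMISSION_NO_CARP" && state == "NO_HISTORY") {
    return("CHD_NO_CARP")
  }
  state
}

# all within-year outcomes for one state: list of (prob weight, event
# sequence, end state, dead flag)
bf_year_outcomes <- function(pfun, st0) {
  outs <- list()
  emit <- function(w, evs, st, dead) {
    outs[[length(outs) + 1]] <<- list(w = w, events = evs, state = st,
                                      dead = dead)
  }
  p <- pfun(st0)
  emit(1 - sum(p), character(0), st0, FALSE)
  emit(p[["CHD_DEATH"]], "CHD_DEATH", st0, TRUE)
  emit(p[["NON_CHD_DEATH"]], "NON_CHD_DEATH", st0, TRUE)
  # first draw: CHD admission, then up to two CARP follow-ons
  st1 <- bf_step_state(st0, "CHD_ADMISSION_NO_CARP")
  q1 <- pfun(st1)
  w0 <- p[["CHD_ADMISSION_NO_CARP"]]
  emit(w0 * (1 - q1[["CABG"]] - q1[["PCI"]]), "CHD_ADMISSION_NO_CARP", st1, FALSE)
  for (c1 in c("CABG", "PCI")) {
    st2 <- bf_step_state(st1, c1)
    q2 <- pfun(st2)
    w1 <- w0 * q1[[c1]]
    emit(w1 * (1 - q2[["CABG"]] - q2[["PCI"]]),
         c("CHD_ADMISSION_NO_CARP", c1), st2, FALSE)
    for (c2 in c("CABG", "PCI")) {
      emit(w1 * q2[[c2]], c("CHD_ADMISSION_NO_CARP", c1, c2),
           bf_step_state(st2, c2), FALSE)
    }
  }
  # first draw: a CARP, then at most one CARP follow-on (two CARPs max)
  for (c1 in c("CABG", "PCI")) {
    st1 <- bf_step_state(st0, c1)
    q1 <- pfun(st1)
    emit(p[[c1]] * (1 - q1[["CABG"]] - q1[["PCI"]]), c1, st1, FALSE)
    for (c2 in c("CABG", "PCI")) {
      emit(p[[c1]] * q1[[c2]], c(c1, c2), bf_step_state(st1, c2), FALSE)
    }
  }
  outs
}

# expected (year x event) counts for one person by exhaustive path expansion
bf_person_counts <- function(sex, age0, state0, table, years) {
  counts <- matrix(0, length(years), 5,
                   dimnames = list(as.character(years), event_types()))
  recurse <- function(t, age, st, w) {
    if (t > length(years) || age >= 80 || w == 0) return()
    pfun <- function(s) {
      vapply(event_types(),
             function(e) get_risk(table, years[t], sex, age, s, e),
             numeric(1))
    }
    for (o in bf_year_outcomes(pfun, st)) {
      for (ev in o$events) {
        counts[t, ev] <<- counts[t, ev] + w * o$w
      }
      if (!o$dead && o$w > 0) recurse(t + 1, age + 1, o$state, w * o$w)
    }
  }
  recurse(1, age0, state0, 1)
  counts
}

bf_expected_counts <- function(cohort, table, start_year, end_year) {
  years <- start_year:end_year
  counts <- matrix(0, length(years), 5,
                   dimnames = list(as.character(years), event_types()))
  for (i in seq_len(nrow(cohort$persons))) {
    p <- cohort$persons[i, ]
    counts <- counts + bf_person_counts(p$sex, p$age, p$state, table, years)
  }
  counts
}

# expected_counts() result reshaped to the same matrix layout
expected_as_matrix <- function(exp_df) {
  years <- sort(unique(exp_df$year))
  m <- matrix(0, length(years), 5,
              dimnames = list(as.character(years), event_types()))
  m[cbind(match(exp_df$year, years), match(exp_df$event, event_types()))] <-
    exp_df$expected
  m
}
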