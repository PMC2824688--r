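# Synthetic baseline cohorts and risk-table histories.
#
# The generator emulates the *qualitative* structure of the real inputs
# (linked hospital-record risk estimates are not publicly available): CHD
# admission, CABG and CHD-death risks declining over calendar time, PCI risk
# rising, all risks increasing with age and higher in males, and CHD-admission
# risk the dominant incidence component. Coefficients are package defaults on
# the logit scale, documented as qualitative emulation, not estimates.

#' Configuration for the synthetic-data generator
#'
#' All risk probabilities are produced as
#' `plogis(intercept[event] + age_slope * (band_midpoint - 55) +
#' male_effect * [male] + state_effect[state] + year_slope[event] *
#' (year - 2000) + noise)`, so they lie in (0, 1) by construction. The
#' history-state prevalence in the cohort follows
#' `P(any history | age) = plogis(history_intercept + history_age_slope * age)`,
#' split among the three history states by `history_split`.
#'
#' @param n_persons Cohort size.
#' @param proportion_male Probability a person is male (default 0.5).
#' @param age_band_weights Sampling weights for the nine 5-year bands,
#'   default linearly decreasing from band 35-39 to 75-79.
#' @param history_intercept,history_age_slope Logistic coefficients for
#'   `P(any CHD/CARP history | age)` (defaults -6.0 and 0.07 per year).
#' @param history_split Conditional split of "any history" among
#'   `CHD_NO_CARP`, `PCI_NO_CABG`, `CABG_HISTORY` (must sum to 1).
#' @param risk_intercepts Named logit-scale intercepts per event.
#' @param age_slope Logit increase per year of age (default 0.08).
#' @param male_effect Logit increase for males (default 0.5).
#' @param state_effects Named logit offsets per history state, applied to the
#'   four CHD-related events (non-CHD death is state-independent).
#' @param year_slopes Named logit change per calendar year per event
#'   (defaults: CHD admission -0.03, CABG -0.05, PCI +0.06, CHD death -0.04,
#'   non-CHD death -0.01 — declining incidence components, rising PCI).
#' @param noise_sd Observation noise s.d. on the logit scale (default 0.02).
#' @param baseline_year Cohort snapshot year (default 2001).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_persons = 10000L,
                             proportion_male = 0.5,
                             age_band_weights = seq(9, 1, length.out = 9),
                             history_intercept = -6.0,
                             history_age_slope = 0.07,
                             history_split = c(CHD_NO_CARP = 0.5,
                                               PCI_NO_CABG = 0.3,
                                               CABG_HISTORY = 0.2),
                             risk_intercepts = c(CHD_ADMISSION_NO_CARP = -4.0,
                                                 CABG = -6.0,
                                                 PCI = -5.5,
                                                 CHD_DEATH = -5.5,
                                                 NON_CHD_DEATH = -4.5),
                             age_slope = 0.08,
                             male_effect = 0.5,
                             state_effects = c(NO_HISTORY = 0,
                                               CHD_NO_CARP = 0.8,
                                               PCI_NO_CABG = 0.6,
                                               CABG_HISTORY = 0.7),
                             year_slopes = c(CHD_ADMISSION_NO_CARP = -0.03,
                                             CABG = -0.05,
                                             PCI = 0.06,
                                             CHD_DEATH = -0.04,
                                             NON_CHD_DEATH = -0.01),
                             noise_sd = 0.02,
                             baseline_year = 2001L) {
  if (n_persons < 1) stop("n_persons must be at least 1", call. = FALSE)
  if (proportion_male < 0 || proportion_male > 1) {
    stop("proportion_male must lie in [0, 1]", call. = FALSE)
  }
  if (length(age_band_weights) != length(AGE_BANDS) ||
      any(age_band_weights < 0) || sum(age_band_weights) <= 0) {
    stop("age_band_weights must be 9 non-negative weights with positive sum",
         call. = FALSE)
  }
  if (!setequal(names(history_split),
                setdiff(HISTORY_STATES, "NO_HISTORY")) ||
      any(history_split < 0) || abs(sum(history_split) - 1) > 1e-9) {
    stop("history_split must be named over the three history states and sum to 1",
         call. = FALSE)
  }
  for (nm in list(risk_intercepts, year_slopes)) {
    if (!setequal(names(nm), EVENT_TYPES)) {
      stop("risk_intercepts and year_slopes must be named over the five events",
           call. = FALSE)
    }
  }
  if (!setequal(names(state_effects), HISTORY_STATES)) {
    stop("state_effects must be named over the four history states", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(n_persons = as.integer(n_persons),
                 proportion_male = proportion_male,
                 age_band_weights = age_band_weights,
                 history_intercept = history_intercept,
                 history_age_slope = history_age_slope,
                 history_split = history_split[setdiff(HISTORY_STATES, "NO_HISTORY")],
                 risk_intercepts = risk_intercepts[EVENT_TYPES],
                 age_slope = age_slope,
                 male_effect = male_effect,
                 state_effects = state_effects[HISTORY_STATES],
                 year_slopes = year_slopes[EVENT_TYPES],
                 noise_sd = noise_sd,
                 baseline_year = as.integer(baseline_year)),
            class = "synthetic_config")
}

#' Generate a synthetic baseline cohort
#'
#' Samples sex, age (band weights, then uniform within band) and CHD/CARP
#' history state (age-dependent logistic prevalence of any history, split by
#' the configured proportions) for `n_persons` members. Fully reproducible
#' under a fixed seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return A [baseline_cohort()].
#' @export
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(as.integer(seed))
  n <- config$n_persons
  sex <- ifelse(stats::runif(n) < config$proportion_male, "male", "female")
  band_i <- sample.int(length(AGE_BANDS), n, replace = TRUE,
                       prob = config$age_band_weights / sum(config$age_band_weights))
  age <- AGE_BAND_LOWER[band_i] + sample.int(5L, n, replace = TRUE) - 1L
  p_hist <- stats::plogis(config$history_intercept +
                            config$history_age_slope * age)
  has_hist <- stats::runif(n) < p_hist
  state <- rep("NO_HISTORY", n)
  n_hist <- sum(has_hist)
  if (n_hist > 0) {
    state[has_hist] <- sample(names(config$history_split), n_hist,
                              replace = TRUE, prob = config$history_split)
  }
  persons <- data.frame(id = sprintf("P%06d", seq_len(n)),
                        sex = sex, age = age, state = state)
  baseline_cohort(persons, baseline_year = config$baseline_year)
}

# Deterministic part of the risk formula (noise excluded), on the logit scale.
risk_linear_predictor <- function(config, year, sex, age_band, state, event) {
  mid <- AGE_BAND_LOWER[match(age_band, AGE_BANDS)] + 2
  state_eff <- ifelse(event == "NON_CHD_DEATH", 0,
                      config$state_effects[state])
  config$risk_intercepts[event] +
    config$age_slope * (mid - 55) +
    config$male_effect * (sex == "male") +
    state_eff +
    config$year_slopes[event] * (year - 2000)
}

#' Generate a synthetic annual risk-table history
#'
#' Evaluates the configured logistic risk model over every
#' (year, sex, age band, state, event) cell, adding N(0, `noise_sd`)
#' observation noise on the logit scale. With the default coefficients the
#' generated history shows declining CHD-admission, CABG and CHD-death risks,
#' rising PCI risk, risks increasing with age and higher in males, and
#' CHD-admission risk dominating the other incidence components — the
#' qualitative pattern of the observed 1990-2000 estimates.
#'
#' @param config A [synthetic_config()].
#' @param years Calendar years to generate (default `1990:2000`).
#' @param seed Integer seed (used for the observation noise).
#' @return A [risk_table()] passing [validate_table()].
#' @export
generate_risk_history <- function(config, years = 1990:2000, seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(years) == 0) stop("years must be non-empty", call. = FALSE)
  set.seed(as.integer(seed))
  grid <- expand.grid(year = as.integer(years), sex = SEXES,
                      age_band = AGE_BANDS, state = HISTORY_STATES,
                      event = EVENT_TYPES, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  lp <- risk_linear_predictor(config, grid$year, grid$sex, grid$age_band,
                              grid$state, grid$event)
  if (config$noise_sd > 0) {
    lp <- lp + stats::rnorm(nrow(grid), sd = config$noise_sd)
  }
  grid$probability <- stats::plogis(as.numeric(lp))
  tab <- risk_table(grid, years_covered = years)
  rep_ <- validate_table(tab)
  if (nrow(rep_) > 0) {
    stop("synthetic risk configuration produces an invalid table ",
         "(competing-risk sums exceed 1); use smaller risk_intercepts",
         call. = FALSE)
  }
  tab
}
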