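# Core enumerations: CHD/CARP history states, annual event types, age bands.

# Dominance order, lowest to highest: once a person reaches a higher state they
# never move back down.
HISTORY_STATES <- c("NO_HISTORY", "CHD_NO_CARP", "PCI_NO_CABG", "CABG_HISTORY")

EVENT_TYPES <- c("CHD_ADMISSION_NO_CARP", "CABG", "PCI", "CHD_DEATH", "NON_CHD_DEATH")
CARP_EVENTS <- c("CABG", "PCI")
DEATH_EVENTS <- c("CHD_DEATH", "NON_CHD_DEATH")

SEXES <- c("male", "female")

AGE_BAND_LOWER <- seq(35L, 75L, by = 5L)
AGE_BANDS <- sprintf("%d-%d", AGE_BAND_LOWER, AGE_BAND_LOWER + 4L)
AGE_MIN <- 35L
AGE_CAP <- 80L # simulated until attained age reaches this; 79 is the last simulated age

#' CHD/CARP history states
#'
#' The four mutually exclusive history states a cohort member can occupy,
#' returned in dominance order from lowest (`NO_HISTORY`) to highest
#' (`CABG_HISTORY`). A person's state only ever moves up this order: a CABG at
#' any time places (and keeps) a person in `CABG_HISTORY` regardless of any
#' PCIs, a PCI without prior CABG gives `PCI_NO_CABG`, and a CHD admission
#' without a revascularization procedure gives `CHD_NO_CARP`.
#'
#' @return Character vector of the four state codes.
#' @export
#' @examples
#' history_states()
history_states <- function() HISTORY_STATES

#' Recognised annual event types
#'
#' The five events a cohort member may experience within a simulated year:
#' a CHD hospital admission without a revascularization procedure, a CABG,
#' a PCI, CHD death and non-CHD death. The two death events are absorbing.
#'
#' @return Character vector of the five event codes.
#' @export
event_types <- function() EVENT_TYPES

#' Five-year age band labels
#'
#' Risk tables are stratified by 5-year age band from 35-39 to 75-79;
#' a person's single-year attained age is mapped to its band at lookup time.
#'
#' @return Character vector of the nine band labels ("35-39", ..., "75-79").
#' @export
age_bands <- function() AGE_BANDS

#' Map single-year age to its 5-year band label
#'
#' @param age Integer vector of ages; must lie in 35-79.
#' @return Character vector of band labels.
#' @export
#' @examples
#' age_to_band(c(35, 57, 79))
age_to_band <- function(age) {
  if (any(is.na(age)) || any(age < AGE_MIN | age >= AGE_CAP)) {
    stop("age outside the supported range 35-79", call. = FALSE)
  }
  AGE_BANDS[(as.integer(age) - AGE_MIN) %/% 5L + 1L]
}

# State reached immediately after experiencing `event` in `state` (vectorised).
# Deaths leave the history state unchanged; the person is simply removed.
state_after_event <- function(state, event) {
  out <- state
  adm <- event == "CHD_ADMISSION_NO_CARP"
  out[adm & state == "NO_HISTORY"] <- "CHD_NO_CARP"
  out[event == "CABG"] <- "CABG_HISTORY"
  pci <- event == "PCI"
  out[pci & state != "CABG_HISTORY"] <- "PCI_NO_CABG"
  out
}

check_codes <- function(x, valid, what) {
  bad <- setdiff(unique(as.character(x)), valid)
  if (length(bad) > 0) {
    stop(sprintf("unknown %s code(s): %s", what, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}
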