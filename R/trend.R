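# Linear trend fitting over recent observed risks and extrapolation of the
# fitted lines into the projection horizon.

#' Fit a linear trend to one risk cell
#'
#' Ordinary least squares on the probability scale through the observed
#' (year, probability) points of one (sex, age band, state, event) cell. The
#' returned `level` is the *fitted* value at the reference year (the last
#' observation year), not the raw observation there, so projection and
#' level-off scenarios both work from the fitted line.
#'
#' @param years Integer vector of observation years (at least two distinct;
#'   the packaged workflow uses 1998-2000).
#' @param probabilities Observed probabilities, same length, each in `[0, 1]`.
#' @return An object of class `linear_trend`: list with `reference_year`,
#'   `level` (fitted probability at the reference year) and `slope`
#'   (probability units per year).
#' @export
#' @examples
#' fit_linear_trend(1998:2000, c(0.10, 0.09, 0.08)) # slope -0.01, level 0.08
fit_linear_trend <- function(years, probabilities) {
  if (length(years) != length(probabilities)) {
    stop("years and probabilities must have equal length", call. = FALSE)
  }
  if (length(unique(years)) < 2) {
    stop("need observations for at least two distinct years", call. = FALSE)
  }
  if (any(is.na(probabilities)) || any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  x <- years - mean(years)
  slope <- sum(x * (probabilities - mean(probabilities))) / sum(x^2)
  ref <- max(years)
  level <- mean(probabilities) + slope * (ref - mean(years))
  structure(list(reference_year = as.integer(ref), level = level, slope = slope),
            class = "linear_trend")
}

#' @export
print.linear_trend <- function(x, ...) {
  cat(sprintf("Linear trend: level %.6g at %d, slope %.6g per year\n",
              x$level, x$reference_year, x$slope))
  invisible(x)
}

#' Fit linear trends for every cell of a risk table
#'
#' Applies [fit_linear_trend()] to each (sex, age band, state, event) cell of
#' `table` over the years in `fit_years` (the three most recent observed
#' years, 1998-2000, in the published analysis).
#'
#' @param table A [risk_table()] covering all of `fit_years`.
#' @param fit_years Years to fit over (default `1998:2000`).
#' @return A `trend_table`: data frame with columns `sex`, `age_band`, `state`,
#'   `event`, `reference_year`, `level`, `slope`, one row per cell.
#' @export
fit_trends <- function(table, fit_years = 1998:2000) {
  stopifnot(inherits(table, "risk_table"))
  missing_years <- setdiff(fit_years, unique(table$year))
  if (length(missing_years) > 0) {
    stop("risk table does not cover fit year(s): ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  sub <- table[table$year %in% fit_years, , drop = FALSE]
  cells <- unique(sub[c("sex", "age_band", "state", "event")])
  cell_id <- function(df) paste(df$sex, df$age_band, df$state, df$event, sep = "|")
  # observations as a cells x years matrix, vectorised closed-form OLS
  obs <- matrix(NA_real_, nrow = nrow(cells), ncol = length(fit_years))
  for (j in seq_along(fit_years)) {
    yr <- sub[sub$year == fit_years[j], , drop = FALSE]
    obs[match(cell_id(yr), cell_id(cells)), j] <- yr$probability
  }
  if (any(is.na(obs))) {
    bad <- which(is.na(obs), arr.ind = TRUE)[1, ]
    stop(sprintf("incomplete risk table: cell (%s) has no entry for year %d",
                 gsub("\\|", ", ", cell_id(cells)[bad[1]]), fit_years[bad[2]]),
         call. = FALSE)
  }
  x <- fit_years - mean(fit_years)
  ybar <- rowMeans(obs)
  slope <- as.numeric(obs %*% x) / sum(x^2)
  ref <- max(fit_years)
  level <- ybar + slope * (ref - mean(fit_years))
  out <- cbind(cells,
               data.frame(reference_year = as.integer(ref),
                          level = level, slope = slope))
  rownames(out) <- NULL
  structure(out, class = c("trend_table", "data.frame"))
}

#' Project fitted trends into future years
#'
#' Extrapolates each cell's fitted line:
#' `value(year) = clamp(level + slope * (year - reference_year), floor, cap)`.
#' Clamping events are recorded in the `"clamping"` attribute of the result
#' (one row per clamped cell-year). If any (year, stratum) cell of the
#' projected table has event probabilities summing above 1, projection fails
#' and lists the offending cells.
#'
#' @param trends A `trend_table` from [fit_trends()].
#' @param years Projection years (default `2001:2010`).
#' @param floor Lower clamp for projected probabilities (default 0).
#' @param cap Upper clamp (default 1).
#' @return A [risk_table()] covering `years`.
#' @export
project_risks <- function(trends, years = 2001:2010, floor = 0, cap = 1) {
  stopifnot(inherits(trends, "data.frame"),
            all(c("level", "slope", "reference_year") %in% names(trends)))
  if (floor < 0 || cap > 1 || floor > cap) {
    stop("require 0 <= floor <= cap <= 1", call. = FALSE)
  }
  n <- nrow(trends)
  out <- trends[rep(seq_len(n), times = length(years)),
                c("sex", "age_band", "state", "event")]
  out$year <- rep(as.integer(years), each = n)
  raw <- rep(trends$level, times = length(years)) +
    rep(trends$slope, times = length(years)) *
    (out$year - rep(trends$reference_year, times = length(years)))
  out$probability <- pmin(pmax(raw, floor), cap)
  clamped <- which(raw < floor | raw > cap)
  tab <- risk_table(out[c("year", "sex", "age_band", "state", "event",
                          "probability")],
                    years_covered = years)
  check_projection_sums(tab)
  clamp_log <- out[clamped, c("year", "sex", "age_band", "state", "event")]
  clamp_log$raw <- raw[clamped]
  rownames(clamp_log) <- NULL
  attr(tab, "clamping") <- clamp_log
  tab
}

check_projection_sums <- function(tab) {
  rep_ <- validate_table(tab)
  over <- rep_[rep_$type == "competing-risk sum exceeds 1", , drop = FALSE]
  if (nrow(over) > 0) {
    cells <- paste(sprintf("(%d, %s, %s, %s)", over$year, over$sex,
                           over$age_band, over$state), collapse = "; ")
    stop("projected event probabilities sum above 1 in: ", cells, call. = FALSE)
  }
  invisible(tab)
}
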