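#' Cap projected coverage rates below one
#'
#' Projected GMS coverage in the oldest cohorts can exceed 1.00 when the
#' projected eligible count outgrows the projected population (e.g. 105
#' eligible persons against a population of 100 gives a raw rate of 1.05).
#' Any raw rate of 1.00 or more is replaced by the adjustment factor
#' `lambda`, a value strictly below one; rates already below 1.00 pass
#' through unchanged.
#'
#' @param raw_rate Non-negative raw coverage rate(s).
#' @param lambda Adjustment factor in (0, 0.99].
#' @return Adjusted rate(s), all in [0, 1).
#' @examples
#' adjust_coverage(1.05)        # 0.99
#' adjust_coverage(0.80)        # 0.80 (unchanged)
#' adjust_coverage(1.20, 0.95)  # 0.95
#' @export
adjust_coverage <- function(raw_rate, lambda = 0.99) {
  if (length(lambda) != 1 || !is.finite(lambda) || lambda <= 0 || lambda > 0.99) {
    stop("lambda must lie in (0, 0.99]", call. = FALSE)
  }
  if (any(!is.finite(raw_rate)) || any(raw_rate < 0)) {
    stop("raw_rate must be non-negative and finite", call. = FALSE)
  }
  ifelse(raw_rate < 1, raw_rate, lambda)
}

# round half up to whole persons (reporting convention)
round_half_up <- function(x) floor(x + 0.5)

#' Project coverage and eligible persons to future horizons
#'
#' Holds the anchor-year per-stratum eligible counts fixed (the most recent
#' observed coverage data) and divides them by each horizon's projected
#' population to get raw per-stratum coverage; [adjust_coverage()] then caps
#' rates at or above one, and eligible persons are recomputed from the
#' adjusted rate, so a capped stratum's eligible count falls below its
#' population.
#'
#' @param eligible_anchor Eligible persons per stratum in the anchor year
#'   (length-160 vector, [population_table()], or data.frame with `count`).
#' @param populations Named list of [population_table()]s, e.g. from
#'   [generate_population()]; one projection is produced per entry.
#' @param lambda Adjustment factor passed to [adjust_coverage()].
#' @return Named list of `coverage_projection` objects, each with fields
#'   `horizon`, `coverage` (a `coverage` [rate_table()]), `eligible`
#'   (persons per stratum), `national_rate`.
#' @export
project_coverage <- function(eligible_anchor, populations, lambda = 0.99) {
  anchor <- as_stratum_counts(eligible_anchor, "eligible_anchor")
  if (any(anchor < 0)) stop("eligible counts must be non-negative", call. = FALSE)
  stopifnot(is.list(populations), length(populations) >= 1)
  out <- lapply(populations, function(pop) {
    stopifnot(inherits(pop, "population_table"))
    n <- pop$count
    bad <- n == 0 & anchor > 0
    if (any(bad)) {
      stop("zero projected population with positive eligible count in stratum ",
           first_bad_stratum(bad), call. = FALSE)
    }
    raw <- ifelse(n == 0, 0, anchor / n)
    adj <- adjust_coverage(raw, lambda)
    eligible <- round_half_up(adj * n)
    structure(list(
      horizon = attr(pop, "horizon"),
      coverage = rate_table(adj, "coverage"),
      eligible = eligible,
      national_rate = sum(eligible) / sum(n)
    ), class = "coverage_projection")
  })
  names(out) <- names(populations)
  out
}

#' @export
print.coverage_projection <- function(x, ...) {
  cat(sprintf(
    "<coverage_projection %d: national rate %.3f, %s eligible persons>\n",
    x$horizon, x$national_rate, format(sum(x$eligible), big.mark = ",")))
  invisible(x)
}

#' Extrapolate average cost per claimant by compound growth
#'
#' Applies `value * (1 + annual_growth)^(horizon - anchor_year)` per
#' stratum, assuming the historical growth evolution of drug costs
#' continues unchanged.
#'
#' @param base An `avg_cost` [rate_table()] for the anchor year.
#' @param annual_growth Scalar annual growth fraction, or a length-160
#'   per-stratum vector; each must satisfy 1 + growth > 0.
#' @param horizon Target year, at or after `anchor_year`.
#' @param anchor_year Year the base table describes (default 2007).
#' @return An `avg_cost` [rate_table()] at the horizon. Transcribed totals
#'   are scaled by the same factor for scalar growth and dropped otherwise
#'   (their claimant weights are unknown).
#' @export
extrapolate_avg_cost <- function(base, annual_growth, horizon,
                                 anchor_year = 2007) {
  stopifnot(inherits(base, "rate_table"))
  if (horizon < anchor_year) {
    stop("horizon must not precede the anchor year", call. = FALSE)
  }
  g <- as.numeric(annual_growth)
  if (!length(g) %in% c(1L, nrow(base))) {
    stop("annual_growth must be scalar or per-stratum", call. = FALSE)
  }
  if (any(1 + g <= 0)) stop("1 + annual_growth must be positive", call. = FALSE)
  fac <- (1 + g)^(horizon - anchor_year)
  totals <- rate_totals(base)
  totals <- if (length(g) == 1 && !is.null(totals)) {
    lapply(totals, function(t) t * fac)
  }
  rate_table(rate_values(base) * fac, rate_kind(base), totals = totals,
             complete = nrow(base) == 160)
}

#' Fit a historical compound growth rate
#'
#' Geometric mean annual growth of a positive series:
#' `(last / first)^(1 / (last_year - first_year)) - 1`. On a series that
#' compounds exactly this coincides with a log-linear regression slope; it
#' is reported because it is parameter-free.
#'
#' @param series Named numeric vector, names = years, values = national
#'   average cost per claimant (or any positive level series).
#' @return Scalar annual growth fraction.
#' @examples
#' fit_historical_growth(c("2005" = 100, "2007" = 121))  # 0.10
#' @export
fit_historical_growth <- function(series) {
  if (length(series) < 2) stop("need at least two years of data", call. = FALSE)
  if (any(!is.finite(series)) || any(series <= 0)) {
    stop("series values must be positive", call. = FALSE)
  }
  years <- as.numeric(names(series))
  if (anyNA(years)) stop("series must be named by year", call. = FALSE)
  o <- order(years)
  years <- years[o]; v <- as.numeric(series)[o]
  span <- years[length(years)] - years[1]
  if (span <= 0) stop("series must span at least one year", call. = FALSE)
  (v[length(v)] / v[1])^(1 / span) - 1
}
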