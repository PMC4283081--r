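as_stratum_counts <- function(x, what = "counts") {
  v <- if (inherits(x, "population_table")) x$count
       else if (is.data.frame(x)) align_strata(x, "count")
       else as.numeric(x)
  if (length(v) != 160 || anyNA(v)) {
    stop(what, " must cover all 160 strata", call. = FALSE)
  }
  v
}

#' Estimate per-stratum claims rates
#'
#' The claims rate is the proportion of medical-card holders who make at
#' least one claim in the year: claimants / eligible, per stratum. Marginal
#' totals are the eligible-weighted aggregates, so the attached grand total
#' equals total claimants over total eligible.
#'
#' @param claimants,eligible Counts per stratum (length-160 vector in
#'   canonical order, [population_table()], or data.frame with `count`).
#' @return A `claims_rate` [rate_table()] with recomputed weighted totals.
#' @examples
#' # national 2007 figures: 1,225,131 claimants of 1,276,178 card holders
#' round(1225131 / 1276178, 2)  # 0.96
#' @export
estimate_claims_rate <- function(claimants, eligible) {
  cl <- as_stratum_counts(claimants, "claimants")
  el <- as_stratum_counts(eligible, "eligible")
  if (any(el <= 0)) {
    stop("eligible count must be positive in every stratum (first zero: ",
         first_bad_stratum(el <= 0), ")", call. = FALSE)
  }
  if (any(cl > el)) {
    stop("claimants exceed eligible in stratum ",
         first_bad_stratum(cl > el), " (corrupted input?)", call. = FALSE)
  }
  if (any(cl < 0)) stop("claimant counts must be non-negative", call. = FALSE)
  grid <- stratum_grid()
  rate <- cl / el
  key <- paste(grid$region, grid$gender, sep = "|")
  by_row <- tapply(cl, key, sum)[unique(key)] /
    tapply(el, key, sum)[unique(key)]
  by_cohort <- tapply(cl, grid$cohort, sum)[gms_cohorts()] /
    tapply(el, grid$cohort, sum)[gms_cohorts()]
  rate_table(rate, "claims_rate",
             totals = list(by_row = by_row, by_cohort = by_cohort,
                           grand = sum(cl) / sum(el)))
}

#' Estimate per-stratum average cost per claimant
#'
#' Average cost per claimant is the total cost of a stratum's claims divided
#' by its number of claimants. When claimant counts are not supplied, each
#' record is taken to be one claimant (the structure of the synthetic
#' database, which has no person identifier). The grand total is overall
#' cost over overall claimants.
#'
#' @param claims A `claims_db` data.frame (needs `region`, `gender`,
#'   `cohort`, `total_cost`).
#' @param claimants Optional claimant counts per stratum; default: the
#'   number of records per stratum.
#' @param require_complete Require every one of the 160 strata to carry at
#'   least one claim (default TRUE); with FALSE a partial table is returned
#'   for the strata present.
#' @return An `avg_cost` [rate_table()] with recomputed weighted totals.
#' @export
estimate_avg_cost <- function(claims, claimants = NULL,
                              require_complete = TRUE) {
  stopifnot(is.data.frame(claims), "total_cost" %in% names(claims))
  grid <- stratum_grid()
  ids <- stratum_id(grid$region, grid$gender, grid$cohort)
  got <- stratum_id(claims$region, claims$gender, claims$cohort)
  cost <- tapply(claims$total_cost, factor(got, levels = ids), sum)
  n_rec <- tapply(rep(1, nrow(claims)), factor(got, levels = ids), sum)
  cost[is.na(cost)] <- 0
  n_rec[is.na(n_rec)] <- 0
  cl <- if (is.null(claimants)) as.numeric(n_rec)
        else as_stratum_counts(claimants, "claimants")
  empty <- n_rec == 0
  if (require_complete && any(empty)) {
    stop("no claims in stratum ", ids[which(empty)[1]], call. = FALSE)
  }
  if (any(cl[!empty] <= 0)) {
    stop("claimant count must be positive wherever claims exist", call. = FALSE)
  }
  avg <- ifelse(empty, NA_real_, as.numeric(cost) / cl)
  key <- paste(grid$region, grid$gender, sep = "|")
  tot_by <- function(f, lv) {
    tapply(as.numeric(cost), f, sum)[lv] /
      tapply(cl, f, sum)[lv]
  }
  totals <- if (!any(empty)) {
    list(by_row = tot_by(key, unique(key)),
         by_cohort = tot_by(grid$cohort, gms_cohorts()),
         grand = sum(cost) / sum(cl))
  }
  rate_table(data.frame(grid, value = avg), "avg_cost", totals = totals,
             complete = !any(empty))
}

#' Per-stratum standard errors
#'
#' `claims_rate_se` is the binomial standard error sqrt(p(1-p)/n) of an
#' estimated claims rate; `avg_cost_se` is the sample standard deviation of
#' per-record total cost over sqrt(n), per stratum.
#'
#' @param rate A `claims_rate` [rate_table()].
#' @param eligible Eligible counts per stratum (the binomial denominators).
#' @return Numeric vector of length 160, canonical order.
#' @export
claims_rate_se <- function(rate, eligible) {
  p <- rate_values(rate)
  n <- as_stratum_counts(eligible, "eligible")
  sqrt(p * (1 - p) / n)
}

#' @rdname claims_rate_se
#' @param claims A `claims_db` data.frame.
#' @export
avg_cost_se <- function(claims) {
  grid <- stratum_grid()
  ids <- stratum_id(grid$region, grid$gender, grid$cohort)
  got <- factor(stratum_id(claims$region, claims$gender, claims$cohort),
                levels = ids)
  s <- tapply(claims$total_cost, got, stats::sd)
  n <- tapply(rep(1, nrow(claims)), got, sum)
  as.numeric(s) / sqrt(as.numeric(n))
}

#' Build minimum / mean / maximum scenarios from a 95 per cent CI
#'
#' The minimum scenario is the point table minus 1.96 standard errors and
#' the maximum the point table plus 1.96 standard errors, clamped to the
#' table kind's domain afterwards ([0, 1] for rates and coverage, strictly
#' positive for costs). A message notes how many cells were clamped.
#'
#' @param point A [rate_table()] of point estimates.
#' @param dispersion Per-stratum standard errors (length 160, canonical
#'   order), all non-negative.
#' @param z Normal quantile (default 1.96; samples are large enough that a
#'   t correction is immaterial).
#' @return A list of class `scenario_set` with components `minimum`, `mean`,
#'   `maximum` (rate tables of the same kind) and `method = "ci95"`.
#' @export
ci95_scenarios <- function(point, dispersion, z = 1.96) {
  stopifnot(inherits(point, "rate_table"))
  se <- as.numeric(dispersion)
  if (length(se) != nrow(point)) {
    stop("dispersion must supply one standard error per stratum", call. = FALSE)
  }
  if (anyNA(se) || any(se < 0)) {
    stop("standard errors must be non-negative", call. = FALSE)
  }
  v <- rate_values(point)
  kind <- rate_kind(point)
  clamp <- function(x) {
    if (kind %in% c("claims_rate", "coverage")) pmin(pmax(x, 0), 1)
    else pmax(x, .Machine$double.eps)
  }
  lo_raw <- v - z * se
  hi_raw <- v + z * se
  lo <- clamp(lo_raw)
  hi <- clamp(hi_raw)
  n_clamped <- sum(lo != lo_raw) + sum(hi != hi_raw)
  if (n_clamped > 0) {
    message("ci95_scenarios: ", n_clamped, " bound(s) clamped to the ",
            kind, " domain")
  }
  mk <- function(x) rate_table(x, kind, complete = nrow(point) == 160)
  structure(list(minimum = mk(lo), mean = mk(v), maximum = mk(hi),
                 method = "ci95"),
            class = "scenario_set")
}

#' Build scenarios from historical extremes
#'
#' Offsets a point table by the gap between a historical series' extremes
#' and its mean, applied uniformly across strata (the national historical
#' record does not resolve strata). Used for coverage scenarios from the
#' 1996-2011 history.
#'
#' @param point A [rate_table()] (typically kind `coverage`).
#' @param history Numeric series of national historical values (e.g. from
#'   [generate_coverage_history()]).
#' @return A `scenario_set` with `method = "historical_extremes"`.
#' @export
historical_scenarios <- function(point, history) {
  stopifnot(inherits(point, "rate_table"), length(history) >= 2)
  v <- rate_values(point)
  kind <- rate_kind(point)
  clamp <- function(x) {
    if (kind %in% c("claims_rate", "coverage")) pmin(pmax(x, 0), 1)
    else pmax(x, .Machine$double.eps)
  }
  lo <- clamp(v + (min(history) - mean(history)))
  hi <- clamp(v + (max(history) - mean(history)))
  mk <- function(x) rate_table(x, kind, complete = nrow(point) == 160)
  structure(list(minimum = mk(lo), mean = mk(v), maximum = mk(hi),
                 method = "historical_extremes"),
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat(sprintf("<scenario_set kind=%s, method=%s>\n",
              rate_kind(x$mean), x$method))
  cat(sprintf("  mean of cells: min %.4f | mean %.4f | max %.4f\n",
              mean(rate_values(x$minimum)), mean(rate_values(x$mean)),
              mean(rate_values(x$maximum))))
  invisible(x)
}

#' Percentage change between two positive values
#'
#' @param start,end Numeric scalars or vectors; `start` must be positive.
#' @return 100 * (end - start) / start, rounded to one decimal place (the
#'   reporting convention for growth figures).
#' @examples
#' percent_change(208756, 422589)  # 102.4
#' @export
percent_change <- function(start, end) {
  if (any(start <= 0)) stop("start must be positive", call. = FALSE)
  round(100 * (end - start) / start, 1)
}
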