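#' Region, gender and age-cohort vocabulary
#'
#' The model stratifies Ireland by the eight former health board regions,
#' two genders and ten age cohorts, giving 160 region-gender-age (RGA)
#' strata. The enumerations are closed and ordered: regions in the order the
#' 2007 claims tables list them, cohorts by ascending age.
#'
#' @return Character vector of level labels.
#' @export
gms_regions <- function() {
  c("Eastern", "Midland", "Mid-Western", "North-Eastern",
    "North-Western", "South-Eastern", "Southern", "Western")
}

#' @rdname gms_regions
#' @export
gms_genders <- function() c("male", "female")

#' @rdname gms_regions
#' @export
gms_cohorts <- function() {
  c("0-11", "12-15", "16-24", "25-34", "35-44",
    "45-54", "55-64", "65-69", "70-74", "75+")
}

#' Enumerate the 160 strata in canonical order
#'
#' Canonical order is region-major, then gender, then cohort: the order in
#' which the printed tables list cells row by row. Every stratified object in
#' the package is stored and addressed in this order, but the public contract
#' is always the (region, gender, cohort) triple, never a position.
#'
#' @return A data.frame with factor columns `region`, `gender`, `cohort`
#'   and 160 rows.
#' @examples
#' nrow(stratum_grid())  # 160
#' @export
stratum_grid <- function() {
  data.frame(
    region = factor(rep(gms_regions(), each = 20), levels = gms_regions()),
    gender = factor(rep(rep(gms_genders(), each = 10), 8), levels = gms_genders()),
    cohort = factor(rep(gms_cohorts(), 16), levels = gms_cohorts())
  )
}

# "region|gender|cohort" id for joining stratified inputs; internal only.
stratum_id <- function(region, gender, cohort) {
  paste(as.character(region), as.character(gender), as.character(cohort),
        sep = "|")
}

# Align a (region, gender, cohort, <value>) data.frame onto the canonical
# 160-row grid; returns the value vector with NA where a stratum is absent.
align_strata <- function(df, value_col = "value") {
  grid <- stratum_grid()
  ids <- stratum_id(grid$region, grid$gender, grid$cohort)
  got <- stratum_id(df$region, df$gender, df$cohort)
  if (anyDuplicated(got)) {
    stop("duplicated stratum: ", got[duplicated(got)][1], call. = FALSE)
  }
  unknown <- setdiff(got, ids)
  if (length(unknown)) {
    stop("unknown stratum: ", unknown[1], call. = FALSE)
  }
  df[[value_col]][match(ids, got)]
}

rate_table_kinds <- c("claims_rate", "coverage", "avg_cost")

check_rate_domain <- function(values, kind, where = "value") {
  bad <- !is.finite(values)
  if (any(bad)) {
    stop("non-finite ", where, " for stratum ",
         first_bad_stratum(bad), call. = FALSE)
  }
  if (kind %in% c("claims_rate", "coverage")) {
    bad <- values < 0 | values > 1
    if (any(bad)) {
      stop(kind, " value out of [0, 1] (", values[bad][1], ") for stratum ",
           first_bad_stratum(bad), call. = FALSE)
    }
  } else {
    bad <- values <= 0
    if (any(bad)) {
      stop("avg_cost value must be positive (", values[bad][1],
           ") for stratum ", first_bad_stratum(bad), call. = FALSE)
    }
  }
  invisible(values)
}

first_bad_stratum <- function(bad) {
  grid <- stratum_grid()
  stratum_id(grid$region, grid$gender, grid$cohort)[which(bad)[1]]
}

#' Construct a stratified rate table
#'
#' A rate table holds one value per RGA stratum: a claims rate (fraction of
#' eligible persons who claim), a coverage rate (fraction of the population
#' holding a medical card), or an average cost per claimant in euro. Rates
#' live in [0, 1]; costs are strictly positive. Printed marginal totals from
#' a source table may be attached as transcribed; they are never recomputed
#' silently (see [validate_consistency()]).
#'
#' @param values Either a data.frame with columns `region`, `gender`,
#'   `cohort`, `value`, or a numeric vector of length 160 in canonical
#'   [stratum_grid()] order.
#' @param kind One of `"claims_rate"`, `"coverage"`, `"avg_cost"`.
#' @param totals Optional list with components `by_row` (named by
#'   "region|gender"), `by_cohort` (named by cohort label) and `grand`,
#'   carrying transcribed marginal totals.
#' @param complete Require all 160 strata (default). Partial tables are
#'   permitted for intermediate computations only.
#' @return An object of class `rate_table`: a data.frame in canonical order
#'   with attributes `kind` and `totals`.
#' @export
rate_table <- function(values, kind = rate_table_kinds, totals = NULL,
                       complete = TRUE) {
  kind <- match.arg(kind, rate_table_kinds)
  grid <- stratum_grid()
  if (is.data.frame(values)) {
    v <- align_strata(values)
  } else {
    if (length(values) != nrow(grid)) {
      stop("numeric `values` must have length 160 (canonical order)",
           call. = FALSE)
    }
    v <- as.numeric(values)
  }
  missing <- is.na(v)
  if (complete && any(missing)) {
    stop("missing stratum: ", first_bad_stratum(missing), call. = FALSE)
  }
  check_rate_domain(v[!missing], kind)
  out <- grid
  out$value <- v
  if (!complete) out <- out[!missing, , drop = FALSE]
  attr(out, "kind") <- kind
  attr(out, "totals") <- totals
  class(out) <- c("rate_table", "data.frame")
  out
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("<rate_table kind=%s, %d strata%s>\n", rate_kind(x), nrow(x),
              if (is.null(attr(x, "totals"))) "" else ", transcribed totals"))
  wide <- stats::reshape(
    as.data.frame(x), idvar = c("region", "gender"),
    timevar = "cohort", direction = "wide"
  )
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Accessors for rate tables
#'
#' @param table A [rate_table()].
#' @param region,gender,cohort Stratum coordinates.
#' @return `stratum_value` returns the scalar cell value; `rate_values` the
#'   full numeric vector in canonical order; `rate_kind` the table kind;
#'   `rate_totals` the transcribed totals (or NULL).
#' @export
stratum_value <- function(table, region, gender, cohort) {
  stopifnot(inherits(table, "rate_table"))
  hit <- table$region == region & table$gender == gender & table$cohort == cohort
  if (!any(hit)) {
    stop("no such stratum: ", stratum_id(region, gender, cohort), call. = FALSE)
  }
  table$value[hit]
}

#' @rdname stratum_value
#' @export
rate_values <- function(table) {
  stopifnot(inherits(table, "rate_table"))
  table$value
}

#' @rdname stratum_value
#' @export
rate_kind <- function(table) attr(table, "kind")

#' @rdname stratum_value
#' @export
rate_totals <- function(table) attr(table, "totals")

#' Construct a stratified population table
#'
#' @param counts A data.frame with columns `region`, `gender`, `cohort`,
#'   `count` (non-negative integers), or a numeric vector of length 160 in
#'   canonical order.
#' @param horizon Projection year, one of 2007, 2011, 2016, 2021, 2026.
#' @return Object of class `population_table` (a data.frame in canonical
#'   order with attribute `horizon`).
#' @export
population_table <- function(counts, horizon) {
  horizon <- as.integer(horizon)
  if (!horizon %in% c(2007L, 2011L, 2016L, 2021L, 2026L)) {
    stop("horizon must be one of 2007, 2011, 2016, 2021, 2026", call. = FALSE)
  }
  grid <- stratum_grid()
  if (is.data.frame(counts)) {
    v <- align_strata(counts, "count")
  } else {
    stopifnot(length(counts) == nrow(grid))
    v <- as.numeric(counts)
  }
  if (anyNA(v)) stop("missing stratum: ", first_bad_stratum(is.na(v)), call. = FALSE)
  if (any(v < 0) || any(v != round(v))) {
    stop("population counts must be non-negative integers", call. = FALSE)
  }
  if (sum(v) <= 0) stop("population grand total must be positive", call. = FALSE)
  out <- grid
  out$count <- v
  attr(out, "horizon") <- horizon
  class(out) <- c("population_table", "data.frame")
  out
}

#' @export
print.population_table <- function(x, ...) {
  cat(sprintf("<population_table horizon=%d, total=%s persons>\n",
              attr(x, "horizon"), format(sum(x$count), big.mark = ",")))
  by_cohort <- tapply(x$count, x$cohort, sum)
  print(by_cohort)
  invisible(x)
}

#' @rdname population_table
#' @param table A `population_table`.
#' @export
population_counts <- function(table) {
  stopifnot(inherits(table, "population_table"))
  table$count
}
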