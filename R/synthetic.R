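# Child-stream seeds: one root seed per config, one fixed offset per
# generator, so adding a generator never perturbs another's sample path.
# Kept below 2^31 - 1 for set.seed().
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(seed) * 48271 + stream * 8191) %% 2147483647)
}

local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Configuration for the synthetic PCRS/CSO emulator
#'
#' Bundles every knob of the synthetic-data generators with the defaults
#' calibrated to the 2007 study conditions: sampling 100 claims per stratum
#' per month (192,000 records in all), per-claimant costs centred on the
#' 2007 average-cost table, claim probabilities from the 2007 claims-rate
#' table, a 4.3 million base population growing 32.6 per cent by 2026 with
#' the over-70 cohorts roughly doubling, and a national coverage history
#' spanning 1996-2011 anchored at 30.1 per cent (2007) and 36.9 per cent
#' (2011).
#'
#' @param seed Root RNG seed (mandatory). Each generator draws from its own
#'   child stream derived from this seed.
#' @param records_per_cell_per_month Claims sampled per stratum per month.
#' @param months Months to generate (default all twelve).
#' @param cost_means `avg_cost` [rate_table()] of per-claimant cost means.
#' @param cost_cv Relative dispersion (CV) of per-record total cost.
#' @param claim_probability `claims_rate` [rate_table()] used when drawing
#'   claimant counts from eligible counts.
#' @param population_2007_total Base-year national population (persons).
#' @param region_shares,gender_split,cohort_shares Base-year composition;
#'   normalised internally to sum to one.
#' @param overall_growth_2026 National population multiplier 2007 to 2026.
#' @param cohort_growth_2026 Named multipliers 2007 to 2026 for cohorts with
#'   an explicit growth target; unnamed cohorts absorb the residual growth.
#' @param region_share_2026 Named end-of-horizon region shares for regions
#'   whose share drifts; others hold their base share (before renormalising
#'   within cohorts).
#' @param population_jitter_sd Lognormal sd of the cell-level perturbation
#'   applied to each cell's growth increment before totals are rescaled.
#' @param coverage_history_range `(min, mean, max)` of the national coverage
#'   series 1996-2011.
#' @param coverage_anchors Named per-year coverage values forced exactly
#'   (default: 0.301 in 2007, 0.369 in 2011).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             records_per_cell_per_month = 100,
                             months = 1:12,
                             cost_means = NULL,
                             cost_cv = 0.30,
                             claim_probability = NULL,
                             population_2007_total = 4300000,
                             region_shares = c(
                               "Eastern" = 0.355, "Midland" = 0.060,
                               "Mid-Western" = 0.085, "North-Eastern" = 0.095,
                               "North-Western" = 0.060, "South-Eastern" = 0.105,
                               "Southern" = 0.146, "Western" = 0.094),
                             gender_split = c(male = 0.5, female = 0.5),
                             cohort_shares = c(
                               "0-11" = 0.170, "12-15" = 0.055,
                               "16-24" = 0.130, "25-34" = 0.170,
                               "35-44" = 0.145, "45-54" = 0.125,
                               "55-64" = 0.085,
                               # 65-69 takes the exact complement so the
                               # configured 75+ head count survives the
                               # normalisation to unit total
                               "65-69" = 1 - 0.915 - 208756 / 4300000,
                               "70-74" = 0.035, "75+" = 208756 / 4300000),
                             overall_growth_2026 = 1.326,
                             cohort_growth_2026 = c(
                               "70-74" = 1.854, "75+" = 422589 / 208756),
                             region_share_2026 = c(
                               "Eastern" = 0.382, "Southern" = 0.136),
                             population_jitter_sd = 0.02,
                             coverage_history_range = c(
                               min = 0.28, mean = 0.31, max = 0.369),
                             coverage_anchors = c(
                               "2007" = 0.301, "2011" = 0.369)) {
  if (missing(seed)) stop("a root `seed` is mandatory", call. = FALSE)
  if (is.null(cost_means)) {
    cost_means <- load_rate_table(gms_fixture("avg_cost_2007.csv"), "avg_cost")
  }
  if (is.null(claim_probability)) {
    claim_probability <- load_rate_table(gms_fixture("claims_rate_2007.csv"),
                                         "claims_rate")
  }
  if (records_per_cell_per_month < 1 ||
      records_per_cell_per_month != round(records_per_cell_per_month)) {
    stop("records_per_cell_per_month must be a positive integer", call. = FALSE)
  }
  stopifnot(all(months %in% 1:12), cost_cv >= 0)
  if (overall_growth_2026 <= 0 || any(cohort_growth_2026 <= 0)) {
    stop("growth multipliers must be positive", call. = FALSE)
  }
  r <- coverage_history_range
  if (length(r) != 3 || any(r < 0) || any(r > 1)) {
    stop("coverage_history_range must be three values in [0, 1]", call. = FALSE)
  }
  if (!(r[1] <= r[2] && r[2] <= r[3])) {
    stop("coverage_history_range must be ordered min <= mean <= max",
         call. = FALSE)
  }
  structure(list(
    seed = seed,
    records_per_cell_per_month = as.integer(records_per_cell_per_month),
    months = as.integer(months),
    cost_means = cost_means, cost_cv = cost_cv,
    claim_probability = claim_probability,
    population_2007_total = population_2007_total,
    region_shares = region_shares / sum(region_shares),
    gender_split = gender_split / sum(gender_split),
    cohort_shares = cohort_shares / sum(cohort_shares),
    overall_growth_2026 = overall_growth_2026,
    cohort_growth_2026 = cohort_growth_2026,
    region_share_2026 = region_share_2026,
    population_jitter_sd = population_jitter_sd,
    coverage_history_range = stats::setNames(as.numeric(r),
                                             c("min", "mean", "max")),
    coverage_anchors = coverage_anchors
  ), class = "synthetic_config")
}

#' Generate a synthetic PCRS-like claims database
#'
#' Emulates the structure of the study's sample claims extract: a fixed
#' number of claim records per stratum per month, each carrying the cost
#' decomposition (ingredient cost, VAT, dispensing fee, total) and item and
#' form counts. Per-record total cost is lognormal with the stratum's
#' configured mean and relative dispersion `cost_cv` (drug costs are
#' positive and strongly right-skewed); the components are split
#' deterministically as approximately 80 per cent ingredient cost, 15 per
#' cent dispensing fee and 5 per cent VAT, with the rounding residual folded
#' into the ingredient cost so that additivity holds exactly to the cent.
#'
#' @param config A [synthetic_config()].
#' @return A data.frame of class `claims_db`: one row per claim record with
#'   columns `month`, `region`, `gender`, `cohort`, `ingredient_cost`,
#'   `vat`, `dispensing_fee`, `total_cost`, `n_items`, `n_forms`. The
#'   default configuration yields 100 x 160 x 12 = 192,000 records.
#' @export
generate_claims_db <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  grid <- stratum_grid()
  k <- config$records_per_cell_per_month
  months <- config$months
  n_cell <- nrow(grid) * length(months)
  n <- n_cell * k

  idx <- rep(seq_len(nrow(grid)), times = length(months) * k)
  month <- rep(rep(months, each = nrow(grid)), times = k)

  mu <- rate_values(config$cost_means)
  cv <- config$cost_cv
  sdlog <- sqrt(log1p(cv^2))
  meanlog <- log(mu) - sdlog^2 / 2

  total <- local_seed(child_seed(config$seed, 11), {
    if (cv == 0) mu[idx] else stats::rlnorm(n, meanlog[idx], sdlog)
  })
  total <- pmax(round(total, 2), 0.01)
  vat <- round(0.05 * total, 2)
  fee <- round(0.15 * total, 2)
  ingredient <- round(total - vat - fee, 2)

  n_items <- local_seed(child_seed(config$seed, 15),
                        1L + stats::rgeom(n, 1 / 3))

  out <- data.frame(
    month = month,
    region = grid$region[idx], gender = grid$gender[idx],
    cohort = grid$cohort[idx],
    ingredient_cost = ingredient, vat = vat, dispensing_fee = fee,
    total_cost = total, n_items = n_items, n_forms = 1L
  )
  out <- out[order(out$month, idx), ]
  rownames(out) <- NULL
  class(out) <- c("claims_db", "data.frame")
  out
}

# Largest-remainder rounding of non-negative reals to integers with an
# exact integer sum.
round_preserve_sum <- function(x, target = round(sum(x))) {
  f <- floor(x)
  short <- as.integer(round(target - sum(f)))
  if (short > 0) {
    up <- order(x - f, decreasing = TRUE)[seq_len(short)]
    f[up] <- f[up] + 1
  } else if (short < 0) {
    down <- order(x - f)[seq_len(-short)]
    f[down] <- f[down] - 1
  }
  f
}

# Interpolated growth multiplier: geometric path from 1 (2007) to m (2026).
interp_mult <- function(m, year) m^((year - 2007) / 19)

#' Generate stratified population projections
#'
#' Builds a base-2007 stratified population from the configured region,
#' gender and cohort composition and projects it to 2011, 2016, 2021 and
#' 2026 along geometric growth paths. Cohorts with an explicit 2026
#' multiplier (by default the 70-74 and 75+ cohorts, which roughly double)
#' hit their targets exactly; the remaining cohorts share the residual so
#' the national total obeys the configured overall growth exactly. Cell
#' counts receive a small seeded lognormal perturbation of their growth
#' increment before cohort totals are rescaled, so aggregates are exact
#' while cells are heterogeneous; with all multipliers equal to one every
#' horizon reproduces the base year identically.
#'
#' @param config A [synthetic_config()].
#' @return Named list of [population_table()]s for horizons 2007, 2011,
#'   2016, 2021 and 2026.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  grid <- stratum_grid()
  regions <- gms_regions(); cohorts <- gms_cohorts()

  base_real <- config$population_2007_total *
    config$region_shares[as.character(grid$region)] *
    config$gender_split[as.character(grid$gender)] *
    config$cohort_shares[as.character(grid$cohort)]
  # round hierarchically: cohort totals first (largest remainder over the
  # grand total), then cells within each cohort, so a cohort configured to
  # an exact head count (e.g. 208,756 in 75+) gets it exactly
  base_cohort_int <- round_preserve_sum(
    tapply(base_real, grid$cohort, sum)[gms_cohorts()],
    round(config$population_2007_total))
  base <- numeric(nrow(grid))
  for (co in gms_cohorts()) {
    sel <- grid$cohort == co
    base[sel] <- round_preserve_sum(base_real[sel], base_cohort_int[[co]])
  }

  horizons <- c(2007L, 2011L, 2016L, 2021L, 2026L)
  jitter <- local_seed(child_seed(config$seed, 12), {
    lapply(horizons[-1], function(h)
      stats::rlnorm(nrow(grid), 0, config$population_jitter_sd))
  })
  names(jitter) <- as.character(horizons[-1])

  base_share_r <- config$region_shares
  out <- list("2007" = population_table(
    data.frame(grid, count = base), 2007))

  for (h in horizons[-1]) {
    overall <- interp_mult(config$overall_growth_2026, h)
    grand_target <- round(config$population_2007_total * overall)

    base_cohort <- tapply(base, grid$cohort, sum)[cohorts]
    fixed <- names(config$cohort_growth_2026)
    t_cohort <- stats::setNames(numeric(length(cohorts)), cohorts)
    t_cohort[fixed] <- base_cohort[fixed] *
      interp_mult(config$cohort_growth_2026, h)[fixed]
    free <- setdiff(cohorts, fixed)
    resid <- grand_target - sum(t_cohort[fixed])
    t_cohort[free] <- resid * base_cohort[free] / sum(base_cohort[free])
    t_cohort <- round_preserve_sum(t_cohort, grand_target)

    # region drift factor, applied within cohorts then renormalised
    rf <- stats::setNames(rep(1, length(regions)), regions)
    drift <- names(config$region_share_2026)
    rf[drift] <- (config$region_share_2026[drift] / base_share_r[drift])^
      ((h - 2007) / 19)

    counts <- numeric(nrow(grid))
    jit <- jitter[[as.character(h)]]
    for (co in cohorts) {
      sel <- grid$cohort == co
      m_cell <- (t_cohort[[co]] / base_cohort[[co]]) *
        rf[as.character(grid$region[sel])]
      # perturb the growth increment, not the level: identity growth stays exact
      m_jit <- 1 + (m_cell - 1) * jit[sel]
      w <- base[sel] * m_jit
      counts[sel] <- round_preserve_sum(w * t_cohort[[co]] / sum(w),
                                        t_cohort[[co]])
    }
    out[[as.character(h)]] <- population_table(
      data.frame(grid, count = counts), h)
  }
  out
}

#' Generate a national GMS coverage history
#'
#' Emits one national coverage rate per year 1996-2011, constructed so the
#' series minimum, mean and maximum equal the configured triple exactly
#' (rather than sampling and hoping): the minimum is placed in 1996, the
#' maximum in the latest non-anchored year (2011 when it is anchored at the
#' maximum), anchored years are forced to their configured values, and the
#' remaining years receive a seeded zero-sum perturbation around the level
#' that delivers the exact mean, bounded away from the extremes.
#'
#' @param config A [synthetic_config()].
#' @return Named numeric vector of length 16 (years 1996-2011).
#' @export
generate_coverage_history <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  years <- 1996:2011
  r <- config$coverage_history_range
  v <- stats::setNames(rep(NA_real_, length(years)), years)

  anchors <- config$coverage_anchors
  if (length(anchors)) {
    if (any(anchors < r[["min"]] - 1e-12 | anchors > r[["max"]] + 1e-12)) {
      stop("coverage anchors must lie within coverage_history_range",
           call. = FALSE)
    }
    v[names(anchors)] <- anchors
  }
  if (r[["min"]] == r[["max"]]) {
    v[] <- r[["min"]]
    return(v)
  }
  # place extremes in years not already pinned elsewhere
  if (!any(abs(stats::na.omit(v) - r[["max"]]) < 1e-12)) {
    free_years <- names(v)[is.na(v)]
    v[free_years[length(free_years)]] <- r[["max"]]
  }
  if (!any(abs(stats::na.omit(v) - r[["min"]]) < 1e-12)) {
    free_years <- names(v)[is.na(v)]
    v[free_years[1]] <- r[["min"]]
  }
  free <- which(is.na(v))
  n_free <- length(free)
  target_sum <- r[["mean"]] * length(years) - sum(v[-free])
  base <- target_sum / n_free
  if (base < r[["min"]] - 1e-12 || base > r[["max"]] + 1e-12) {
    stop("coverage_history_range mean is unreachable with these anchors",
         call. = FALSE)
  }
  amp <- 0.9 * min(base - r[["min"]], r[["max"]] - base)
  noise <- local_seed(child_seed(config$seed, 13),
                      stats::runif(n_free, -1, 1))
  noise <- noise - mean(noise)
  if (max(abs(noise)) > 0) noise <- noise / max(abs(noise))
  v[free] <- base + amp * noise
  v
}

#' Draw claimant counts from eligible counts
#'
#' Binomial sampling of the number of claimants per stratum given eligible
#' (medical-card holding) persons and the per-stratum claim probability.
#'
#' @param eligible Numeric vector of length 160 (canonical order), a
#'   [population_table()], or a data.frame with a `count` column: eligible
#'   persons per stratum.
#' @param claim_probability A `claims_rate` [rate_table()].
#' @param seed RNG seed.
#' @return Integer vector of claimants per stratum, canonical order.
#' @export
generate_claimant_counts <- function(eligible, claim_probability, seed) {
  el <- if (inherits(eligible, "population_table")) eligible$count
        else if (is.data.frame(eligible)) align_strata(eligible, "count")
        else as.numeric(eligible)
  stopifnot(length(el) == 160, all(el >= 0))
  p <- rate_values(claim_probability)
  local_seed(child_seed(seed, 14),
             stats::rbinom(length(el), size = as.integer(round(el)), prob = p))
}

#' Write a claims database to CSV
#'
#' @param db A `claims_db` data.frame from [generate_claims_db()].
#' @param path Output path.
#' @param provenance Optional one-line provenance string.
#' @return `path`, invisibly.
#' @export
write_claims_db <- function(db, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# synthetic PCRS-like claims database%s",
                     if (is.null(provenance)) "" else paste0("; ", provenance)),
             con)
  utils::write.csv(as.data.frame(db), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a claims database written by [write_claims_db()]
#'
#' @param path CSV path.
#' @return A `claims_db` data.frame.
#' @export
read_claims_db <- function(path) {
  db <- utils::read.csv(path, comment.char = "#")
  db$region <- factor(db$region, levels = gms_regions())
  db$gender <- factor(db$gender, levels = gms_genders())
  db$cohort <- factor(db$cohort, levels = gms_cohorts())
  class(db) <- c("claims_db", "data.frame")
  db
}
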