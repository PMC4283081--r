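#' Empirical class distribution over the RGA strata
#'
#' Converts eligible-person counts (or any non-negative weights) into the
#' empirical probability of finding a person in each region-gender-age
#' class, with the cumulative upper bounds used by the inverse-CDF stratum
#' sampler. Zero-weight strata are retained with zero-width intervals and
#' can never be sampled.
#'
#' @param eligible Weights per stratum: length-160 vector in canonical
#'   order, [population_table()], data.frame with `count`, or a shorter
#'   named-by-id vector for reduced universes in testing.
#' @return A list of class `class_distribution` with `strata` (data.frame of
#'   keys), `probabilities` and `cumulative` (upper bounds, final bound
#'   exactly 1).
#' @export
class_distribution <- function(eligible) {
  if (inherits(eligible, "population_table") || is.data.frame(eligible)) {
    strata <- eligible[, c("region", "gender", "cohort")]
    w <- eligible$count
  } else if (length(eligible) == 160) {
    strata <- stratum_grid()
    w <- as.numeric(eligible)
  } else {
    strata <- data.frame(id = names(eligible))
    w <- stats::setNames(as.numeric(eligible), names(eligible))
  }
  if (anyNA(w) || any(w < 0)) {
    stop("weights must be non-negative", call. = FALSE)
  }
  if (sum(w) <= 0) stop("total weight must be positive", call. = FALSE)
  p <- w / sum(w)
  cum <- unname(cumsum(p))
  cum[length(cum)] <- 1  # kill accumulated float error at the top
  structure(list(strata = strata, probabilities = p, cumulative = cum),
            class = "class_distribution")
}

#' @export
print.class_distribution <- function(x, ...) {
  cat(sprintf("<class_distribution over %d strata, %d with positive weight>\n",
              length(x$probabilities), sum(x$probabilities > 0)))
  invisible(x)
}

#' Inverse-CDF sampling of a stratum
#'
#' Maps uniform variates to strata by the cumulative class probabilities:
#' a draw `u` selects the first stratum whose cumulative upper bound
#' exceeds `u` (half-open intervals `[lower, upper)`), so `u = 0` selects
#' the first stratum with positive weight and zero-width intervals are
#' skipped.
#'
#' @param u Uniform variate(s) in `[0, 1)`.
#' @param dist A [class_distribution()].
#' @return Integer index (or vector of indices) into `dist$strata`.
#' @export
sample_stratum <- function(u, dist) {
  stopifnot(inherits(dist, "class_distribution"))
  if (any(u < 0) || any(u >= 1)) stop("u must lie in [0, 1)", call. = FALSE)
  # findInterval counts bounds <= u, so +1 gives the first bound > u
  findInterval(u, dist$cumulative) + 1L
}

#' Specification of one Monte Carlo run
#'
#' @param horizon Projection year the inputs describe.
#' @param scenario 1 (minimum), 2 (mean) or 3 (maximum).
#' @param n_iterations Number of draws (default 100,000).
#' @param noise_sd_fraction Standard deviation of the multiplicative error
#'   ensemble as a fraction of cost (default 0.05, i.e. 5 per cent of cost).
#' @param seed RNG seed (mandatory).
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(horizon, scenario = 2, n_iterations = 100000,
                            noise_sd_fraction = 0.05, seed) {
  if (missing(seed)) stop("a `seed` is mandatory", call. = FALSE)
  stopifnot(scenario %in% 1:3, n_iterations >= 1, noise_sd_fraction >= 0)
  structure(list(horizon = as.integer(horizon), scenario = as.integer(scenario),
                 n_iterations = as.integer(n_iterations),
                 noise_sd_fraction = noise_sd_fraction, seed = seed),
            class = "simulation_spec")
}

deterministic_core <- function(coverage, claims_rate, avg_cost) {
  core <- rate_values(coverage) * rate_values(claims_rate) *
    rate_values(avg_cost)
  if (length(core) != 160 ||
      nrow(coverage) != nrow(claims_rate) ||
      nrow(claims_rate) != nrow(avg_cost)) {
    stop("coverage, claims_rate and avg_cost must cover the same strata",
         call. = FALSE)
  }
  core
}

#' Draw perturbed per-person costs for a stratum
#'
#' The deterministic core of a stratum is coverage x claims rate x average
#' cost per claimant: the expected pharmacy cost per population member of
#' that stratum. Each draw multiplies the core by `(1 + e)` with
#' `e ~ Normal(0, noise_sd_fraction)` — the error ensemble has standard
#' deviation proportional to cost — and non-positive results are redrawn
#' (at 5 per cent relative noise this effectively never fires).
#'
#' @param region,gender,cohort Stratum coordinates.
#' @param coverage,claims_rate,avg_cost Complete [rate_table()]s.
#' @param noise_sd_fraction Relative noise SD (default 0.05).
#' @param n Number of draws (default 1).
#' @return Numeric vector of `n` positive per-person costs. The caller is
#'   responsible for seeding.
#' @export
draw_cost <- function(region, gender, cohort, coverage, claims_rate, avg_cost,
                      noise_sd_fraction = 0.05, n = 1) {
  core <- stratum_value(coverage, region, gender, cohort) *
    stratum_value(claims_rate, region, gender, cohort) *
    stratum_value(avg_cost, region, gender, cohort)
  if (core <= 0) {
    stop("stratum ", stratum_id(region, gender, cohort),
         " has zero deterministic cost; give it zero sampling weight instead",
         call. = FALSE)
  }
  draws <- core * (1 + stats::rnorm(n, 0, noise_sd_fraction))
  bad <- draws <= 0
  while (any(bad)) {
    draws[bad] <- core * (1 + stats::rnorm(sum(bad), 0, noise_sd_fraction))
    bad <- draws <= 0
  }
  draws
}

#' Run the stratified Monte Carlo cost simulation
#'
#' Each iteration samples an RGA stratum by its cumulative empirical
#' probability (inverse-CDF over the eligible-person shares) and draws that
#' stratum's per-person cost perturbed by the Gaussian error ensemble.
#' Uniform variates (stratum choice) and normal variates (noise) come from
#' separate child streams of the spec seed, so sample paths are stable.
#'
#' @param spec A [simulation_spec()].
#' @param eligible Sampling weights per stratum (eligible persons by
#'   default; pass population counts to weight by population instead).
#' @param coverage,claims_rate,avg_cost Complete [rate_table()]s for the
#'   spec's horizon and scenario.
#' @return A list of class `simulation_result`: `draws` (data.frame with
#'   `region`, `gender`, `cohort`, `cost`), `spec`, and
#'   `deterministic_expectation` = sum over strata of p_s x core_s.
#' @export
simulate_costs <- function(spec, eligible, coverage, claims_rate, avg_cost) {
  stopifnot(inherits(spec, "simulation_spec"))
  dist <- class_distribution(eligible)
  core <- deterministic_core(coverage, claims_rate, avg_cost)
  sampled_zero <- dist$probabilities > 0 & core <= 0
  if (any(sampled_zero)) {
    stop("stratum ", first_bad_stratum(sampled_zero),
         " has positive sampling weight but zero deterministic cost",
         call. = FALSE)
  }
  n <- spec$n_iterations
  u <- local_seed(child_seed(spec$seed, 21), stats::runif(n))
  idx <- sample_stratum(u, dist)
  eps <- local_seed(child_seed(spec$seed, 22),
                    stats::rnorm(n, 0, spec$noise_sd_fraction))
  cost <- core[idx] * (1 + eps)
  bad <- which(cost <= 0)
  if (length(bad)) {
    redraw <- local_seed(child_seed(spec$seed, 23), {
      sapply(bad, function(i) {
        repeat {
          e <- stats::rnorm(1, 0, spec$noise_sd_fraction)
          if (core[idx[i]] * (1 + e) > 0) return(core[idx[i]] * (1 + e))
        }
      })
    })
    cost[bad] <- redraw
  }
  grid <- dist$strata
  structure(list(
    draws = data.frame(grid[idx, , drop = FALSE], cost = cost,
                       row.names = NULL),
    spec = spec,
    deterministic_expectation = sum(dist$probabilities * core)
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result: %s draws, horizon %d, scenario %d>\n",
    format(nrow(x$draws), big.mark = ","), x$spec$horizon, x$spec$scenario))
  cat(sprintf("  ensemble mean %.2f | deterministic expectation %.2f\n",
              mean(x$draws$cost), x$deterministic_expectation))
  invisible(x)
}

#' Deterministic total scheme cost
#'
#' Sum over strata of population x coverage x claims rate x average cost
#' per claimant, in euro. Identically equal to the population-weighted mean
#' per-person deterministic cost times the total population.
#'
#' @param population A [population_table()] (or length-160 count vector).
#' @param coverage,claims_rate,avg_cost Complete [rate_table()]s.
#' @return Total cost in euro (scalar).
#' @export
total_cost <- function(population, coverage, claims_rate, avg_cost) {
  n <- as_stratum_counts(population, "population")
  core <- deterministic_core(coverage, claims_rate, avg_cost)
  sum(n * core)
}
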