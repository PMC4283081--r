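#' Descriptive statistics of a draw ensemble
#'
#' The nine-statistic summary used for simulation output: n, mean, standard
#' error of the mean, standard deviation, minimum, quartiles, median and
#' maximum. Quantiles use linear interpolation of order statistics, type 6
#' by default (the Minitab convention); the type is exposed because no
#' universal convention exists.
#'
#' @param draws Numeric vector of simulated costs (or a
#'   `simulation_result`, whose `cost` column is used), length >= 1.
#' @param quantile_type Passed to [stats::quantile()] (default 6).
#' @return A one-row data.frame of class `descriptive_row` with columns
#'   `n`, `mean`, `se_mean`, `st_dev`, `min`, `q1`, `median`, `q3`, `max`.
#' @examples
#' describe_draws(c(1, 2, 3, 4, 5))
#' @export
describe_draws <- function(draws, quantile_type = 6) {
  if (inherits(draws, "simulation_result")) draws <- draws$draws$cost
  x <- as.numeric(draws)
  if (length(x) == 0 || anyNA(x)) {
    stop("draws must be a non-empty numeric vector", call. = FALSE)
  }
  n <- length(x)
  s <- if (n > 1) stats::sd(x) else 0
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = quantile_type,
                       names = FALSE)
  out <- data.frame(n = n, mean = mean(x), se_mean = s / sqrt(n), st_dev = s,
                    min = min(x), q1 = q[1], median = q[2], q3 = q[3],
                    max = max(x))
  class(out) <- c("descriptive_row", "data.frame")
  out
}

#' Main-effects decomposition of simulated costs
#'
#' Mean simulated cost by level of each categorical factor (region, gender,
#' age cohort), the grand mean, and a ranking of the three factors by the
#' range of their level means — the drivers-of-cost view of the ensemble.
#' Levels with no draws are reported as absent, not zero. When per-stratum
#' weights are supplied (eligible persons), level means are weighted means
#' of per-stratum draw means, so the weighted recombination of any factor's
#' level means reproduces the weighted grand mean exactly.
#'
#' @param result A `simulation_result` (draws must carry stratum labels).
#' @param weights Optional per-stratum weights, length 160 canonical order.
#' @return A list of class `main_effects`: `by_region`, `by_gender`,
#'   `by_cohort` (named means over populated levels), `grand_mean`,
#'   `ranges` (named, sorted decreasing), `ranking` (factor names, most
#'   influential first).
#' @export
main_effects <- function(result, weights = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  d <- result$draws
  if (!all(c("region", "gender", "cohort") %in% names(d))) {
    stop("draws do not carry stratum labels", call. = FALSE)
  }

  if (is.null(weights)) {
    level_means <- function(f) {
      m <- tapply(d$cost, d[[f]], mean)
      m[!is.na(m)]
    }
    grand <- mean(d$cost)
  } else {
    w <- as.numeric(weights)
    stopifnot(length(w) == 160, all(w >= 0))
    grid <- stratum_grid()
    ids <- stratum_id(grid$region, grid$gender, grid$cohort)
    got <- factor(stratum_id(d$region, d$gender, d$cohort), levels = ids)
    m_s <- tapply(d$cost, got, mean)
    have <- !is.na(m_s) & w > 0
    level_means <- function(f) {
      lv <- as.character(grid[[f]])
      num <- tapply((w * m_s)[have], lv[have], sum)
      den <- tapply(w[have], lv[have], sum)
      out <- num / den
      out[order(match(names(out), levels(grid[[f]])))]
    }
    grand <- sum((w * m_s)[have]) / sum(w[have])
  }

  by_region <- level_means("region")
  by_gender <- level_means("gender")
  by_cohort <- level_means("cohort")
  ranges <- sort(c(
    region = diff(range(by_region)),
    gender = diff(range(by_gender)),
    cohort = diff(range(by_cohort))
  ), decreasing = TRUE)
  structure(list(by_region = by_region, by_gender = by_gender,
                 by_cohort = by_cohort, grand_mean = grand,
                 ranges = ranges, ranking = names(ranges)),
            class = "main_effects")
}

#' @export
print.main_effects <- function(x, ...) {
  cat("<main_effects>\n")
  cat(sprintf("  grand mean: %.2f\n", x$grand_mean))
  cat("  factor ranges (level-mean max - min), most influential first:\n")
  for (f in x$ranking) {
    cat(sprintf("    %-7s %.2f\n", f, x$ranges[[f]]))
  }
  invisible(x)
}

#' Compare scenarios and horizons
#'
#' One descriptive row per (horizon, scenario) simulation, with the
#' deterministic expectation and, when population tables are given, the
#' deterministic total scheme cost in euro millions.
#'
#' @param results Nested named list: `results[[horizon]][[scenario]]` is a
#'   `simulation_result`. A flat named list of results is also accepted.
#' @param quantile_type Passed to [describe_draws()].
#' @return A data.frame with columns `horizon`, `scenario`, the nine
#'   descriptive statistics, and `deterministic_expectation`.
#' @export
scenario_report <- function(results, quantile_type = 6) {
  flat <- list()
  for (nm in names(results)) {
    el <- results[[nm]]
    if (inherits(el, "simulation_result")) {
      flat[[nm]] <- el
    } else {
      for (nm2 in names(el)) flat[[paste(nm, nm2, sep = ".")]] <- el[[nm2]]
    }
  }
  if (!length(flat)) stop("no simulation results supplied", call. = FALSE)
  rows <- lapply(flat, function(r) {
    d <- describe_draws(r, quantile_type = quantile_type)
    cbind(data.frame(horizon = r$spec$horizon, scenario = r$spec$scenario),
          d, data.frame(deterministic_expectation = r$deterministic_expectation))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$horizon, out$scenario), ]
  rownames(out) <- NULL
  out
}

#' Binned histogram table of a draw ensemble
#'
#' Tabular stand-in for a histogram figure: equal-width bins over the draw
#' range with counts and relative frequencies, suitable for CSV export.
#'
#' @param draws Numeric vector or `simulation_result`.
#' @param bins Number of equal-width bins (default 30).
#' @return Data.frame with `lower`, `upper`, `count`, `freq`.
#' @export
hist_table <- function(draws, bins = 30) {
  if (inherits(draws, "simulation_result")) draws <- draws$draws$cost
  stopifnot(length(draws) >= 1, bins >= 1)
  breaks <- seq(min(draws), max(draws), length.out = bins + 1)
  if (breaks[1] == breaks[length(breaks)]) {
    return(data.frame(lower = breaks[1], upper = breaks[1],
                      count = length(draws), freq = 1))
  }
  cut_idx <- findInterval(draws, breaks, rightmost.closed = TRUE)
  counts <- tabulate(cut_idx, nbins = bins)
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
             count = counts, freq = counts / length(draws))
}

#' Write a data.frame as CSV with a provenance comment
#'
#' @param df Data.frame to write.
#' @param path Output path.
#' @param provenance One-line provenance string (seed, config hash).
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gmscostsim report%s",
                     if (is.null(provenance)) "" else paste0("; ", provenance)),
             con)
  utils::write.csv(as.data.frame(df), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
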