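#' Locate a packaged fixture table
#'
#' @param name Fixture file name, e.g. `"claims_rate_2007.csv"`.
#' @return Absolute path to the installed fixture.
#' @export
gms_fixture <- function(name) {
  path <- system.file("extdata", name, package = "gmscostsim")
  if (!nzchar(path)) stop("no packaged fixture named ", name, call. = FALSE)
  path
}

#' Load a stratified rate table from CSV
#'
#' The fixture format is one region-gender row per line with the ten cohort
#' columns in ascending-age order, an optional `total` column holding the
#' printed row total, and an optional final `Total,all` row holding the
#' printed cohort totals and grand total. Lines starting with `#` are
#' transcription notes. Printed totals are attached as transcribed and are
#' checked against recomputed marginals only by [validate_consistency()].
#'
#' @param path CSV file path (see [gms_fixture()] for the packaged tables).
#' @param kind Table kind: `"claims_rate"`, `"coverage"` or `"avg_cost"`.
#' @return A complete, validated [rate_table()].
#' @examples
#' t2 <- load_rate_table(gms_fixture("avg_cost_2007.csv"), "avg_cost")
#' stratum_value(t2, "Eastern", "male", "0-11")  # 228.09
#' @export
load_rate_table <- function(path, kind = rate_table_kinds) {
  kind <- match.arg(kind, rate_table_kinds)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                         colClasses = "character", strip.white = TRUE)
  if (nrow(raw) == 0) stop("no data rows in ", path, call. = FALSE)
  need <- c("region", "gender", gms_cohorts())
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("fixture header missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  is_total_row <- raw$region == "Total"
  body <- raw[!is_total_row, , drop = FALSE]
  if (nrow(body) != 16) {
    stop("expected 16 region-gender data rows, found ", nrow(body),
         call. = FALSE)
  }

  parse_cell <- function(txt, row_label, col) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- is.na(v) & nzchar(txt)
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("malformed numeric token '%s' at row '%s', column '%s'",
                   txt[i], row_label[i], col), call. = FALSE)
    }
    v
  }
  body_label <- paste(body$region, body$gender, sep = "/")

  long <- do.call(rbind, lapply(gms_cohorts(), function(co) {
    data.frame(region = body$region, gender = body$gender, cohort = co,
               value = parse_cell(body[[co]], body_label, co))
  }))

  totals <- NULL
  if ("total" %in% names(raw)) {
    by_row <- parse_cell(body$total, body_label, "total")
    names(by_row) <- paste(body$region, body$gender, sep = "|")
    totals <- list(by_row = by_row)
  }
  if (any(is_total_row)) {
    trow <- raw[is_total_row, , drop = FALSE][1, ]
    by_cohort <- parse_cell(unlist(trow[gms_cohorts()]), rep("Total", 10),
                            "cohort totals")
    names(by_cohort) <- gms_cohorts()
    totals <- c(totals, list(by_cohort = by_cohort))
    if ("total" %in% names(trow)) {
      totals$grand <- parse_cell(trow$total, "Total", "total")
    }
  }

  rate_table(long, kind = kind, totals = totals)
}

#' Write a rate table to CSV
#'
#' Inverse of [load_rate_table()]: cell values round-trip bit-exactly, and
#' transcribed totals (if any) are written back unmodified. A one-line
#' provenance comment records how the file was produced.
#'
#' @param table A [rate_table()], complete over the 160 strata.
#' @param path Output CSV path.
#' @param provenance Optional one-line provenance string (seed, config hash).
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(table, path, provenance = NULL) {
  stopifnot(inherits(table, "rate_table"))
  if (nrow(table) != 160) stop("only complete tables can be written", call. = FALSE)
  num <- function(x) sprintf("%.15g", x)
  totals <- rate_totals(table)
  wide <- matrix(num(table$value), nrow = 16, ncol = 10, byrow = TRUE)
  grid16 <- unique(table[, c("region", "gender")])
  rows <- apply(cbind(as.character(grid16$region), as.character(grid16$gender),
                      wide), 1, paste, collapse = ",")
  header <- c("region", "gender", gms_cohorts())
  if (!is.null(totals$by_row)) {
    header <- c(header, "total")
    rows <- paste(rows, num(totals$by_row), sep = ",")
  }
  lines <- c(
    sprintf("# %s table written by gmscostsim%s", rate_kind(table),
            if (is.null(provenance)) "" else paste0("; ", provenance)),
    paste(header, collapse = ","),
    rows
  )
  if (!is.null(totals$by_cohort)) {
    trow <- paste(c("Total", "all", num(totals$by_cohort),
                    if (!is.null(totals$grand)) num(totals$grand)),
                  collapse = ",")
    lines <- c(lines, trow)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Check transcribed marginal totals against recomputed weighted marginals
#'
#' Recomputes row (region-gender), cohort and grand marginals of a rate table
#' as weighted means of the cell values and compares them with the totals
#' transcribed from the printed source. The printed totals were produced with
#' the source's own claimant weights, which are not published, so mismatches
#' up to `tolerance` are expected; the report flags anything larger. The
#' table is never modified.
#'
#' @param table A [rate_table()] carrying transcribed totals.
#' @param weights A [population_table()], a numeric vector of length 160 in
#'   canonical order, or a data.frame with `region`, `gender`, `cohort`,
#'   `count`. Equal weights reproduce an unweighted mean.
#' @param tolerance Relative tolerance before a marginal is flagged
#'   (default 0.005, i.e. 0.5 per cent).
#' @return A data.frame of class `consistency_report` with one row per
#'   comparable marginal: `margin`, `label`, `transcribed`, `recomputed`,
#'   `rel_diff`, `flagged`.
#' @export
validate_consistency <- function(table, weights, tolerance = 0.005) {
  stopifnot(inherits(table, "rate_table"))
  w <- if (inherits(weights, "population_table")) {
    weights$count
  } else if (is.data.frame(weights)) {
    align_strata(weights, "count")
  } else {
    as.numeric(weights)
  }
  if (length(w) != nrow(table)) {
    stop("weights must cover the table's ", nrow(table), " strata", call. = FALSE)
  }
  if (anyNA(w) || any(w < 0)) stop("weights must be non-negative", call. = FALSE)

  totals <- rate_totals(table)
  wmean <- function(v, wt) sum(v * wt) / sum(wt)
  rows <- list()
  add <- function(margin, label, transcribed, recomputed) {
    rel <- abs(recomputed - transcribed) / abs(transcribed)
    rows[[length(rows) + 1]] <<- data.frame(
      margin = margin, label = label, transcribed = transcribed,
      recomputed = recomputed, rel_diff = rel, flagged = rel > tolerance
    )
  }
  if (!is.null(totals$by_row)) {
    key <- paste(table$region, table$gender, sep = "|")
    for (k in names(totals$by_row)) {
      sel <- key == k
      add("row", k, totals$by_row[[k]], wmean(table$value[sel], w[sel]))
    }
  }
  if (!is.null(totals$by_cohort)) {
    for (co in names(totals$by_cohort)) {
      sel <- table$cohort == co
      add("cohort", co, totals$by_cohort[[co]], wmean(table$value[sel], w[sel]))
    }
  }
  if (!is.null(totals$grand)) {
    add("grand", "grand", totals$grand, wmean(table$value, w))
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(margin = character(), label = character(),
               transcribed = numeric(), recomputed = numeric(),
               rel_diff = numeric(), flagged = logical())
  }
  class(out) <- c("consistency_report", "data.frame")
  out
}

#' @export
print.consistency_report <- function(x, ...) {
  n_flag <- sum(x$flagged)
  cat(sprintf("<consistency_report: %d marginals checked, %d flagged>\n",
              nrow(x), n_flag))
  if (n_flag > 0) print(as.data.frame(x[x$flagged, ]), row.names = FALSE)
  invisible(x)
}
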