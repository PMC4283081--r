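test_that("claims database has the exact configured record structure", {
  cfg <- synthetic_config(seed = 1, records_per_cell_per_month = 1, months = 1)
  db <- generate_claims_db(cfg)
  expect_equal(nrow(db), 160)
  expect_equal(sort(unique(as.character(db$region))), sort(gms_regions()))
  cfg3 <- synthetic_config(seed = 1, records_per_cell_per_month = 3,
                           months = c(1, 7))
  expect_equal(nrow(generate_claims_db(cfg3)), 3 * 160 * 2)
  expect_error(synthetic_config(seed = 1, records_per_cell_per_month = 0),
               "positive integer")
})

test_that("cost components are additive to the cent and counts are sane", {
  cfg <- synthetic_config(seed = 7, records_per_cell_per_month = 5)
  db <- generate_claims_db(cfg)
  expect_true(all(abs(db$ingredient_cost + db$vat + db$dispensing_fee -
                        db$total_cost) < 1e-9))
  expect_true(all(db$total_cost > 0))
  expect_true(all(db$n_items >= db$n_forms))
  expect_true(all(db$n_forms == 1))
  # ingredient cost is approximately 80 per cent of total
  expect_equal(sum(db$ingredient_cost) / sum(db$total_cost), 0.80,
               tolerance = 0.01)
})

test_that("zero-dispersion claims reproduce the configured means exactly", {
  cfg <- synthetic_config(seed = 3, cost_cv = 0,
                          records_per_cell_per_month = 2, months = 1)
  db <- generate_claims_db(cfg)
  em <- db[db$region == "Eastern" & db$gender == "male" & db$cohort == "0-11", ]
  expect_true(all(em$total_cost == 228.09))
  est <- estimate_avg_cost(db)
  expect_equal(rate_values(est), rate_values(table2()), tolerance = 1e-12)
})

test_that("per-stratum sample means converge to the configured means", {
  # 1,200 records per stratum; CLT bound 3 * cv / sqrt(1200) per stratum
  bound <- 3 * 0.30 / sqrt(1200)
  hits <- unlist(lapply(c(11, 12), function(s) {
    cfg <- synthetic_config(seed = s)
    db <- generate_claims_db(cfg)
    est <- rate_values(estimate_avg_cost(db))
    abs(est / rate_values(table2()) - 1) < bound
  }))
  expect_gte(mean(hits), 0.97)
})

test_that("generators are byte-identical under a repeated seed", {
  cfg <- function() synthetic_config(seed = 99, records_per_cell_per_month = 2,
                                     months = 1:2)
  expect_identical(generate_claims_db(cfg()), generate_claims_db(cfg()))
  expect_identical(generate_population(cfg()), generate_population(cfg()))
  expect_identical(generate_coverage_history(cfg()),
                   generate_coverage_history(cfg()))
  # different seed, different draws
  cfg2 <- synthetic_config(seed = 100, records_per_cell_per_month = 2,
                           months = 1:2)
  expect_false(identical(generate_claims_db(cfg())$total_cost,
                         generate_claims_db(cfg2)$total_cost))
})

test_that("population projections obey configured growth exactly", {
  cfg <- synthetic_config(seed = 5)
  pops <- generate_population(cfg)
  tot <- sapply(pops, function(p) sum(p$count))
  expect_identical(tot[["2026"]] / tot[["2007"]], 1.326)
  expect_true(all(diff(tot) > 0))
  # configured 75+ calibration: 208,756 persons in 2007, 422,589 in 2026
  p75 <- sapply(pops, function(p) sum(p$count[p$cohort == "75+"]))
  expect_equal(p75[["2007"]], 208756)
  expect_equal(p75[["2026"]], 422589)
  # integers, no negatives, cohort shares sum to one
  for (p in pops) {
    expect_true(all(p$count >= 0))
    expect_true(all(p$count == round(p$count)))
    shares <- tapply(p$count, p$cohort, sum) / sum(p$count)
    expect_equal(sum(shares), 1, tolerance = 1e-12)
  }
})

test_that("identity growth reproduces the base year at every horizon", {
  cfg <- synthetic_config(seed = 8, overall_growth_2026 = 1,
                          cohort_growth_2026 = c("70-74" = 1, "75+" = 1),
                          region_share_2026 = c("Eastern" = 0.355 / 1.000,
                                                "Southern" = 0.146 / 1.000))
  pops <- generate_population(cfg)
  for (h in c("2011", "2016", "2021", "2026")) {
    expect_identical(pops[[h]]$count, pops[["2007"]]$count)
  }
  expect_error(synthetic_config(seed = 1, overall_growth_2026 = -0.2),
               "positive")
})

test_that("a cohort multiplier moves only that cohort's head count", {
  base <- synthetic_config(seed = 2)
  pops <- generate_population(base)
  p75_2026 <- sum(pops[["2026"]]$count[pops[["2026"]]$cohort == "75+"])
  # explicit multiplier 2.024 against the exact 208,756 base
  cfg <- synthetic_config(seed = 2, cohort_growth_2026 = c("75+" = 2.024))
  p <- generate_population(cfg)[["2026"]]
  expect_equal(sum(p$count[p$cohort == "75+"]), round(208756 * 2.024),
               tolerance = 5 / round(208756 * 2.024))
  expect_false(sum(p$count[p$cohort == "75+"]) == p75_2026)
})

test_that("coverage history matches its configured envelope exactly", {
  cfg <- synthetic_config(seed = 4,
                          coverage_history_range = c(0.28, 0.30, 0.33),
                          coverage_anchors = c("2007" = 0.301))
  v <- generate_coverage_history(cfg)
  expect_equal(length(v), 16)
  expect_equal(names(v), as.character(1996:2011))
  expect_equal(min(v), 0.28, tolerance = 1e-9)
  expect_equal(max(v), 0.33, tolerance = 1e-9)
  expect_equal(mean(v), 0.30, tolerance = 1e-9)
  expect_equal(unname(v[["2007"]]), 0.301)
  expect_true(all(v >= 0 & v <= 1))

  flat <- synthetic_config(seed = 4,
                           coverage_history_range = c(0.3, 0.3, 0.3),
                           coverage_anchors = c("2007" = 0.3))
  expect_true(all(generate_coverage_history(flat) == 0.3))

  expect_error(synthetic_config(seed = 1,
                                coverage_history_range = c(0.3, 0.2, 0.4)),
               "ordered")
  expect_error(synthetic_config(seed = 1,
                                coverage_history_range = c(0.3, 0.5, 1.2)),
               "\\[0, 1\\]")
})

test_that("default coverage history carries the study anchors", {
  v <- generate_coverage_history(synthetic_config(seed = 6))
  expect_equal(unname(v[["2007"]]), 0.301)
  expect_equal(unname(v[["2011"]]), 0.369)
  expect_equal(max(v), 0.369)
})

test_that("claims databases round-trip through CSV", {
  cfg <- synthetic_config(seed = 11, records_per_cell_per_month = 1,
                          months = 1)
  db <- generate_claims_db(cfg)
  f <- tempfile(fileext = ".csv")
  write_claims_db(db, f, provenance = "seed 11")
  back <- read_claims_db(f)
  expect_equal(back$total_cost, db$total_cost)
  expect_equal(as.character(back$region), as.character(db$region))
  expect_equal(back$n_items, db$n_items)
})
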