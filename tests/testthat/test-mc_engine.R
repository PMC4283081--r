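test_that("class distributions turn weights into cumulative probabilities", {
  d <- class_distribution(c(a = 1))
  expect_equal(d$cumulative, 1.0)

  d3 <- class_distribution(c(a = 20, b = 30, c = 50))
  expect_equal(d3$probabilities, c(a = 0.2, b = 0.3, c = 0.5))
  expect_equal(unname(d3$cumulative), c(0.2, 0.5, 1.0))
  expect_identical(d3$cumulative[3], 1)

  u160 <- class_distribution(rep(1, 160))
  expect_true(all(u160$probabilities == 1 / 160))
  expect_equal(sum(u160$probabilities), 1, tolerance = 1e-12)

  expect_error(class_distribution(rep(0, 160)), "positive")
  expect_error(class_distribution(c(a = -1, b = 2)), "non-negative")
})

test_that("inverse-CDF sampling uses half-open intervals and skips zero weight", {
  d <- class_distribution(c(a = 20, b = 30, c = 50))
  expect_equal(sample_stratum(0.0, d), 1L)
  expect_equal(sample_stratum(0.49, d), 2L)
  expect_equal(sample_stratum(0.2, d), 2L)   # lower bound belongs to b
  expect_equal(sample_stratum(0.999, d), 3L)
  expect_error(sample_stratum(1.0, d), "\\[0, 1\\)")
  expect_error(sample_stratum(-0.1, d), "\\[0, 1\\)")

  z <- class_distribution(c(a = 0, b = 2, c = 8))
  expect_equal(sample_stratum(0.0, z), 2L)   # first nonzero-weight stratum
})

test_that("sampling frequencies match class probabilities (chi-square GOF)", {
  d <- class_distribution(c(a = 0.2, b = 0.3, c = 0.5))
  set.seed(77)
  idx <- sample_stratum(runif(100000), d)
  obs <- tabulate(idx, nbins = 3)
  p <- stats::chisq.test(obs, p = c(0.2, 0.3, 0.5))$p.value
  expect_gt(p, 0.01)
})

test_that("draw_cost is the deterministic core perturbed multiplicatively", {
  covr <- flat_table(0.5, "coverage")
  cr <- flat_table(1.0, "claims_rate")
  ac <- flat_table(10, "avg_cost")
  expect_equal(draw_cost("Eastern", "male", "0-11", covr, cr, ac,
                         noise_sd_fraction = 0), 5.0)
  # a zero-coverage stratum has no valid cost draw; it must carry zero
  # sampling weight instead
  expect_error(draw_cost("Eastern", "male", "0-11",
                         flat_table(0, "coverage"), cr, ac),
               "zero sampling weight")
  set.seed(5)
  draws <- draw_cost("Western", "female", "75+", covr, cr, ac, 0.05, n = 1000)
  expect_true(all(draws > 0))
  expect_equal(mean(draws), 5, tolerance = 0.02)
})

test_that("single-stratum ensembles have the configured 5% cost CV", {
  w <- point_mass(1)
  covr <- flat_table(0.5, "coverage")
  cr <- flat_table(1.0, "claims_rate")
  ac <- flat_table(100, "avg_cost")
  res <- simulate_costs(simulation_spec(2016, 2, 100000, seed = 3),
                        w, covr, cr, ac)
  cv <- sd(res$draws$cost) / mean(res$draws$cost)
  expect_equal(100 * cv, 5, tolerance = 0.1 / 5)  # +-0.1 percentage points
  expect_equal(res$deterministic_expectation, 50)
  expect_true(all(res$draws$region == "Eastern"))
})

test_that("one noiseless draw equals the stratum's deterministic cost", {
  res <- simulate_costs(
    simulation_spec(2016, 2, n_iterations = 1, noise_sd_fraction = 0, seed = 1),
    point_mass(7), flat_table(0.4, "coverage"), flat_table(0.9, "claims_rate"),
    flat_table(100, "avg_cost"))
  expect_equal(nrow(res$draws), 1)
  expect_equal(res$draws$cost, 0.4 * 0.9 * 100)
})

test_that("ensemble means converge to the closed-form expectation", {
  cfg <- synthetic_config(seed = 19)
  pops <- generate_population(cfg)
  el <- pops[["2016"]]$count
  covr <- flat_table(0.35, "coverage")
  t1 <- table1(); t2 <- table2()
  for (n in c(1000, 10000, 100000)) {
    res <- simulate_costs(simulation_spec(2016, 2, n, seed = 29),
                          el, covr, t1, t2)
    se <- sd(res$draws$cost) / sqrt(n)
    expect_lt(abs(mean(res$draws$cost) - res$deterministic_expectation),
              3 * se)
  }
})

test_that("identical spec and seed give identical draws", {
  args <- function() list(simulation_spec(2021, 2, 2000, seed = 123),
                          rep(1, 160), flat_table(0.3, "coverage"),
                          table1(), table2())
  r1 <- do.call(simulate_costs, args())
  r2 <- do.call(simulate_costs, args())
  expect_identical(r1$draws, r2$draws)
  r3 <- simulate_costs(simulation_spec(2021, 2, 2000, seed = 124),
                       rep(1, 160), flat_table(0.3, "coverage"),
                       table1(), table2())
  expect_false(identical(r1$draws$cost, r3$draws$cost))
})

test_that("zero-cost strata with positive weight are rejected", {
  covr <- flat_table(0.5, "coverage")
  v <- rep(0.5, 160); v[3] <- 0
  covr0 <- rate_table(v, "coverage")
  expect_error(
    simulate_costs(simulation_spec(2016, 2, 10, seed = 1), rep(1, 160),
                   covr0, table1(), table2()),
    "positive sampling weight but zero deterministic cost")
  # harmless when the same stratum carries no weight
  w <- rep(1, 160); w[3] <- 0
  expect_s3_class(
    simulate_costs(simulation_spec(2016, 2, 10, seed = 1), w,
                   covr0, table1(), table2()),
    "simulation_result")
})

test_that("total scheme cost sums population x coverage x claims x cost", {
  covr <- flat_table(0.5, "coverage")
  cr <- flat_table(1.0, "claims_rate")
  ac <- flat_table(10, "avg_cost")
  pop <- numeric(160); pop[1] <- 100
  expect_equal(total_cost(pop, covr, cr, ac), 500)

  # two strata against element-wise brute force
  pop2 <- numeric(160); pop2[c(1, 42)] <- c(100, 250)
  brute <- 100 * 0.5 * 1 * 10 + 250 * 0.5 * 1 * 10
  expect_equal(total_cost(pop2, covr, cr, ac), brute, tolerance = 1e-9)

  # scale identity: total = per-person expectation x total population
  cfg <- synthetic_config(seed = 37)
  pop3 <- generate_population(cfg)[["2021"]]
  tot <- total_cost(pop3, covr, table1(), table2())
  d <- class_distribution(pop3$count)
  core_mean <- sum(d$probabilities * 0.5 * rate_values(table1()) *
                     rate_values(table2()))
  expect_equal(tot, core_mean * sum(pop3$count), tolerance = 1e-6)
})

test_that("scenario monotonicity holds for deterministic and simulated means", {
  t2 <- table2()
  cfg <- synthetic_config(seed = 43)
  db <- generate_claims_db(cfg)
  sc <- ci95_scenarios(estimate_avg_cost(db), avg_cost_se(db))
  covr <- flat_table(0.35, "coverage")
  el <- rep(1000, 160)
  means <- sapply(c("minimum", "mean", "maximum"), function(s) {
    res <- simulate_costs(simulation_spec(2016, match(s, c("minimum", "mean", "maximum")),
                                          20000, seed = 55),
                          el, covr, table1(), sc[[s]])
    c(sim = mean(res$draws$cost), det = res$deterministic_expectation)
  })
  expect_true(means["det", "minimum"] <= means["det", "mean"])
  expect_true(means["det", "mean"] <= means["det", "maximum"])
  expect_true(means["sim", "minimum"] <= means["sim", "mean"])
  expect_true(means["sim", "mean"] <= means["sim", "maximum"])
})
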