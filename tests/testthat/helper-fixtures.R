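# packaged 2007 tables
table1 <- function() {
  load_rate_table(gms_fixture("claims_rate_2007.csv"), "claims_rate")
}
table2 <- function() {
  load_rate_table(gms_fixture("avg_cost_2007.csv"), "avg_cost")
}

# constant table over the full 160-stratum universe
flat_table <- function(value, kind) rate_table(rep(value, 160), kind)

# point-mass weight vector on one canonical stratum index
point_mass <- function(i) {
  w <- rep(0, 160)
  w[i] <- 1
  w
}

# write fixture lines to a temp csv
tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
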