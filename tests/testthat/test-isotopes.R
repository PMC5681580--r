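test_that("discrimination follows the two-pool mixing form and inverts exactly", {
  expect_equal(discrimination(-8, -8), 0)
  expect_equal(discrimination(-6.32, -25), (-6.32 + 25) / (1 - 25 / 1000))
  expect_equal(round(discrimination(-6.32, -25), 4), 19.1590)
  ## algebraic round trip
  set.seed(2)
  for (i in 1:50) {
    delta <- runif(1, 10, 25); air <- runif(1, -9, -6)
    tree <- d13c_from_discrimination(delta, air)
    expect_equal(discrimination(air, tree), delta, tolerance = 1e-12)
  }
  expect_error(discrimination(-8, -1000), "exceed")
})

test_that("reference extrapolation continues OLS trends and flags new years", {
  ref <- data.frame(year = 1980:2002,
                    d13c_air = -7 - 0.02 * (1980:2002 - 1980),
                    ca = 340 + 1.5 * (1980:2002 - 1980))
  out <- extrapolate_reference(ref)
  expect_identical(max(out$year), 2012L)
  expect_equal(out$d13c_air[out$year == 2012], -7 - 0.02 * 32, tolerance = 1e-10)
  expect_equal(out$ca[out$year == 2012], 340 + 1.5 * 32, tolerance = 1e-10)
  expect_true(all(out$extrapolated[out$year > 2002]))
  expect_false(any(out$extrapolated[out$year <= 2002]))
  ## closed-form check: slope 0.02/yr fit over 1993-2002 puts 2012 at c + 0.38
  ref2 <- data.frame(year = 1993:2002, d13c_air = 0.02 * (1993:2002 - 1993) + 5,
                     ca = rep(300, 10))
  out2 <- extrapolate_reference(ref2)
  expect_equal(out2$d13c_air[out2$year == 2012], 5 + 0.38, tolerance = 1e-10)
  expect_equal(out2$ca[out2$year == 2012], 300, tolerance = 1e-10)  # constant extends
  expect_error(extrapolate_reference(ref2[-3, ]), "missing")
})

test_that("Ci/Ca and iWUE honour the fractionation bounds and arithmetic", {
  expect_equal(as.numeric(ci_over_ca(4.4)), 0)
  expect_equal(as.numeric(ci_over_ca(27)), 1)
  expect_equal(as.numeric(ci_over_ca(15.7)), 0.5)
  flagged <- ci_over_ca(c(3, 28, 15.7))
  expect_identical(attr(flagged, "out_of_range"), c(1L, 2L))
  expect_equal(as.numeric(iwue(400, 240)), 100)
  expect_equal(as.numeric(iwue(400, 400)), 0)
  expect_equal(as.numeric(iwue(296, 0.6 * 296)), 74)
  expect_identical(attr(iwue(300, c(200, 310)), "negative"), 2L)
  expect_error(iwue(-1, 0), "positive")
  ## monotonicity: Ci/Ca increases with discrimination; iWUE falls with Ci
  ds <- seq(5, 26, length.out = 30)
  expect_true(all(diff(as.numeric(ci_over_ca(ds))) > 0))
  cis <- seq(100, 380, length.out = 20)
  expect_true(all(diff(as.numeric(iwue(400, cis))) < 0))
})

make_iso_records <- function(seed, n = 240, period_effect = c(p1 = 0, p2 = 0, p3 = 0),
                             age_fun = function(a) 1.5 * exp(-a / 18), sigma = 0.3) {
  set.seed(seed)
  periods <- names(period_effect)
  df <- data.frame(
    tree_id = sprintf("T%03d", seq_len(n)),
    period = sample(periods, n, replace = TRUE),
    ring_age = runif(n, 5, 140))
  df$delta <- 17 + age_fun(df$ring_age) + period_effect[df$period] +
    rnorm(n, 0, sigma)
  df
}

test_that("age adjustment separates the age profile from period effects", {
  ## age effect only: flat period dependence, age importance dominates
  rec <- make_iso_records(seed = 5)
  adj <- age_adjustment(rec, hold_age = 100, seed = 1)
  expect_lt(diff(range(adj$adjusted$delta_adjusted)), 0.1)
  expect_gt(adj$importance[["ring_age"]], adj$importance[["period"]])
  ## a pure 1-permil period step is recovered
  rec2 <- make_iso_records(seed = 6, period_effect = c(p1 = 0, p2 = 0, p3 = -1))
  adj2 <- age_adjustment(rec2, hold_age = 100, seed = 1)
  a <- setNames(adj2$adjusted$delta_adjusted, adj2$adjusted$period)
  expect_equal(unname(a["p3"] - mean(a[c("p1", "p2")])), -1, tolerance = 0.15)
  ## the fitted age profile tracks the juvenile decline
  prof <- adj$age_profile
  early <- mean(prof$delta_fitted[prof$ring_age <= 15])
  late <- mean(prof$delta_fitted[prof$ring_age >= 80])
  expect_gt(early - late, 0.7)
})

test_that("age adjustment is deterministic under a seed and refuses degenerate input", {
  rec <- make_iso_records(seed = 7, n = 120)
  a1 <- age_adjustment(rec, seed = 99)
  a2 <- age_adjustment(rec, seed = 99)
  expect_identical(a1$adjusted, a2$adjusted)
  one_period <- rec; one_period$period <- "p1"
  expect_error(age_adjustment(one_period, seed = 1), "period")
  young <- rec; young$ring_age <- runif(nrow(rec), 10, 40)
  expect_error(age_adjustment(young, seed = 1), "range")
  expect_error(age_adjustment(rec[1:10, ], seed = 1), "records|period")
})

test_that("physio series: constant discrimination with rising Ca raises Ci and iWUE", {
  ref <- generate_reference(synth_config(seed = 1))
  periods <- c("1895-1904", "1930-1949", "1950-1959", "1993-2002", "2003-2012")
  set.seed(3)
  recs <- do.call(rbind, lapply(periods, function(p) {
    n <- 40
    age <- runif(n, 10, 130)
    air <- mean(extrapolate_reference(ref)$d13c_air[
      match(borealrings:::period_years(p), extrapolate_reference(ref)$year)])
    data.frame(tree_id = sprintf("%s_%02d", p, 1:n), species = "black_spruce",
               period = p, ring_age = age,
               d13c_cellulose = d13c_from_discrimination(18, air) + rnorm(n, 0, 0.02))
  }))
  ph <- physio_series(recs, ref, n_tree = 200, seed = 5)
  ph <- ph[order(ph$period), ]
  expect_lt(diff(range(ph$ci_over_ca)), 0.02)       # near-constant Ci/Ca
  expect_true(all(diff(ph$ci) > 0))                  # Ci rises with Ca
  expect_true(all(diff(ph$iwue) > 0))                # iWUE rises too
  expect_true(all(diff(ph$ca) > 0))
  expect_equal(ph$ci, ph$ci_over_ca * ph$ca, tolerance = 1e-12)
  ## raw discrimination is reported without the cellulose offset; the
  ## gas-exchange chain applies it, so adjusted delta exceeds raw
  expect_true(all(ph$delta_adjusted > ph$delta_raw_mean))
})

test_that("single-record periods yield undefined standard errors", {
  ref <- generate_reference(synth_config(seed = 1))
  periods <- c("1930-1949", "1950-1959", "1993-2002")
  set.seed(4)
  recs <- do.call(rbind, lapply(periods, function(p) {
    n <- if (p == "1993-2002") 1L else 30L
    data.frame(tree_id = paste0(p, "_", seq_len(n)), species = "white_spruce",
               period = p, ring_age = runif(n, 5, 120),
               d13c_cellulose = rnorm(n, -24, 0.3))
  }))
  ph <- physio_series(recs, ref, n_tree = 100, seed = 2)
  expect_true(is.na(ph$delta_raw_se[ph$period == "1993-2002"]))
  expect_false(anyNA(ph$delta_raw_se[ph$period != "1993-2002"]))
})
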