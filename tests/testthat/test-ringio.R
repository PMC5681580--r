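test_that("RWL parsing honours the decadal layout and stop-marker dialects", {
  f <- withr::local_tempfile(fileext = ".rwl")
  writeLines("TST01 1990 100 200 999", f)
  rs <- read_rwl(f)
  expect_length(rs, 1L)
  expect_equal(rs[["TST01"]]$first_year, 1990L)
  expect_equal(rs[["TST01"]]$widths, c(1.00, 2.00))

  writeLines("TST02 1990 1000 2000 -9999", f)
  rs2 <- read_rwl(f)
  expect_equal(rs2[["TST02"]]$widths, c(1.000, 2.000))

  ## an interior 999 in the high-precision dialect is a real 0.999 mm ring
  writeLines("TST03 1990 999 2000 -9999", f)
  expect_equal(read_rwl(f)[["TST03"]]$widths, c(0.999, 2.000))
})

test_that("RWL round-trips widths and years exactly", {
  rs <- small_cohort()$series[1:8]
  ## quantize to the format's 0.001 mm precision first; at that precision
  ## write -> read is the identity
  rs <- ring_set(lapply(rs, function(s) { s$widths <- round(s$widths, 3); s }))
  f <- withr::local_tempfile(fileext = ".rwl")
  write_rwl(rs, f)
  back <- read_rwl(f)
  expect_setequal(names(back), names(rs))
  for (id in names(rs)) {
    expect_equal(back[[id]]$widths, rs[[id]]$widths, tolerance = 1e-12)
    expect_identical(series_years(back[[id]]), series_years(rs[[id]]))
  }
})

test_that("malformed and duplicate RWL input is rejected with location", {
  f <- withr::local_tempfile(fileext = ".rwl")
  writeLines(c("AAA 1990 100 200", "BBB 199x 100"), f)
  expect_error(read_rwl(f), "line 2")
  writeLines(c("AAA 1990 100 110 120", "AAA 1991 200 210"), f)
  expect_error(read_rwl(f), "duplicate|overlap")
})

test_that("geometric missing-radius estimation matches the circle-fit oracle", {
  expect_equal(estimate_missing_radius(20, 10), 10.0)
  expect_equal(estimate_missing_radius(20, 2), 26.0)
  ## oracle: exact circle through the arc's three defining points
  for (case in list(c(20, 10), c(20, 2), c(14, 3.5))) {
    chord <- case[1]; height <- case[2]
    r_fit <- circle_fit_radius(c(-chord / 2, 0), c(0, height), c(chord / 2, 0))
    expect_equal(estimate_missing_radius(chord, height), r_fit, tolerance = 1e-9)
  }
  expect_error(estimate_missing_radius(0, 1), "positive")
  expect_error(estimate_missing_radius(2, 3), "chord")
})

test_that("missing-radius recovery is exact on arcs from known circles", {
  for (R in c(1, 2.5, 10, 37, 64, 100)) {
    for (frac in c(0.1, 0.4, 0.9)) {
      h <- frac * R
      chord <- sqrt((R - h / 2) * 8 * h)
      expect_lt(abs(estimate_missing_radius(chord, h) - R), 1e-6)
    }
  }
})

test_that("missing-ring counts use the first-ten-ring mean and round half to even", {
  s <- ring_series("X", 1900, c(rep(0.5, 10), rep(0.4, 20)))
  expect_identical(estimate_missing_rings(s, 26.0)$missing_rings, 52L)
  expect_identical(estimate_missing_rings(s, 0)$missing_rings, 0L)
  expect_identical(estimate_missing_rings(s, 1.24)$missing_rings, 2L)  # 2.48 -> 2
  expect_identical(estimate_missing_rings(s, 1.25)$missing_rings, 2L)  # 2.5 -> even
  expect_identical(estimate_missing_rings(s, 1.75)$missing_rings, 4L)  # 3.5 -> even
  short <- ring_series("Y", 1900, rep(0.5, 9))
  expect_error(estimate_missing_rings(short, 1), "fewer than 10")
})

test_that("fire filter removes the fire year onward and never touches pre-fire rings", {
  s <- ring_series("F", 1900, seq(0.3, by = 0.01, length.out = 114),
                   fire_year = 1970L)
  out <- apply_fire_filter(s)
  expect_identical(range(series_years(out)), c(1900L, 1969L))
  expect_identical(out$widths, s$widths[1:70])
  expect_identical(apply_fire_filter(ring_series("G", 1900, rep(1, 5))),
                   ring_series("G", 1900, rep(1, 5)))
  pre <- ring_series("H", 1900, rep(1, 5), fire_year = 1899L)
  expect_warning(res <- apply_fire_filter(pre), "dropped")
  expect_null(res)
  ## fire year retained when include_fire_year = FALSE
  out2 <- apply_fire_filter(s, include_fire_year = FALSE)
  expect_identical(max(series_years(out2)), 1970L)
})

test_that("inter-series correlation flags and scores as expected", {
  base <- exp(rnorm(80, 0, 0.3))
  set1 <- ring_set(lapply(1:4, function(i)
    ring_series(paste0("ID", i), 1930, base, pith_present = TRUE)))
  res <- interseries_correlation(set1)
  expect_true(all(abs(res$r - 1) < 1e-10))
  expect_equal(res$mean_r, 1)

  ## a series vs its mirror image around the common mean
  x <- 1 + 0.3 * sin(seq_len(80))
  set2 <- ring_set(ring_series("A", 1930, x, pith_present = TRUE),
                   ring_series("B", 1930, 2 - x, pith_present = TRUE))
  res2 <- interseries_correlation(set2)
  expect_lt(unname(res2$r["A"]), -0.999)

  ## independent white noise: low correlation in nearly all replicates
  set.seed(42)
  hits <- replicate(300, {
    s <- ring_set(ring_series("A", 1930, exp(rnorm(100, 0, 0.3)), pith_present = TRUE),
                  ring_series("B", 1930, exp(rnorm(100, 0, 0.3)), pith_present = TRUE))
    all(abs(interseries_correlation(s)$r) < 0.3)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("loading applies pith correction and excludes series without pith or arc", {
  coh <- small_cohort()
  dir <- withr::local_tempdir()
  paths <- write_synth_dataset(coh, dir)
  rs <- load_ring_data(paths[["rwl"]], paths[["metadata"]])
  expect_identical(length(rs), length(coh$series))
  ## a pith-present tree round-trips widths exactly
  pith_ids <- names(coh$series)[vapply(coh$series, `[[`, TRUE, "pith_present")]
  id <- pith_ids[1L]
  expect_equal(rs[[id]]$widths, coh$series[[id]]$widths, tolerance = 6e-4)
  expect_identical(rs[[id]]$missing_rings, 0L)
  ## a missing-pith tree gets a ring-count estimate near the true count
  ## (biased slightly high: the withheld juvenile rings are wider than the
  ## first ten retained ones)
  tp <- coh$truth$tree_params
  mp <- tp$series_id[tp$missing_rings_true > 0][1L]
  expect_true(abs(rs[[mp]]$missing_rings - tp$missing_rings_true[tp$series_id == mp]) <= 6)
  ## breaking the arc metadata drops the series
  meta <- read.csv(paths[["metadata"]])
  meta$chord_mm[meta$series_id == mp] <- NA
  f2 <- file.path(dir, "meta2.csv")
  write.csv(meta, f2, row.names = FALSE)
  rs2 <- load_ring_data(paths[["rwl"]], f2)
  expect_false(mp %in% names(rs2))
})

test_that("smoothing spline attains its nominal 50% frequency response", {
  n <- 300
  for (P in c(20, 32, 60)) {
    y <- sin(2 * pi * seq_len(n) / P)
    sm <- spline_smooth(y, cutoff = P)
    core <- 100:200  # away from boundaries
    amp <- sqrt(mean(sm[core]^2)) / sqrt(mean(y[core]^2))
    expect_equal(amp, 0.5, tolerance = 0.02)
  }
  ## long wavelengths pass, short are blocked
  slow <- sin(2 * pi * seq_len(n) / 200)
  expect_gt(sqrt(mean(spline_smooth(slow, 32)[100:200]^2)) /
            sqrt(mean(slow[100:200]^2)), 0.95)
  fast <- sin(2 * pi * seq_len(n) / 6)
  expect_lt(sqrt(mean(spline_smooth(fast, 32)[100:200]^2)) /
            sqrt(mean(fast[100:200]^2)), 0.05)
})

test_that("biweight mean is robust, bounded and matches direct iteration", {
  expect_equal(biweight_mean(c(1, 1, 1)), 1)
  expect_equal(biweight_mean(c(0.8, 1.0, 1.2)), 1)  # symmetric 3-point = mean
  v <- c(0.9, 1.0, 1.1, 1.0, 5.0)
  bw <- biweight_mean(v)
  expect_gt(bw, 0.9); expect_lt(bw, 1.1)
  expect_lt(bw, mean(v))
  set.seed(7)
  for (i in 1:200) {
    x <- rnorm(sample(4:40, 1))
    if (i %% 3 == 0) x <- c(x, rnorm(2, mean = 10))  # contaminated
    expect_lt(abs(biweight_mean(x) - biweight_oracle(x)), 1e-9)
    expect_gte(biweight_mean(x), min(x))
    expect_lte(biweight_mean(x), max(x))
  }
  expect_error(biweight_mean(numeric(0)), "empty")
})
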