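test_that("RCS group assignment partitions series and enforces group size", {
  g200 <- assign_rcs_groups(constant_series_set(runif(200, 0.2, 2)), 4L)
  expect_equal(as.integer(table(g200)), rep(50L, 4))
  g100 <- assign_rcs_groups(constant_series_set(runif(100, 0.2, 2)), 4L)
  expect_identical(sort(unique(g100)), 1:2)
  expect_equal(as.integer(table(g100)), rep(50L, 2))
  g30 <- assign_rcs_groups(constant_series_set(runif(30, 0.2, 2)), 4L)
  expect_identical(unique(g30), 1L)
  ## partition: every series in exactly one group, ranked by growth rate
  means <- seq(0.2, 2, length.out = 200)
  g <- assign_rcs_groups(constant_series_set(means), 4L)
  expect_identical(sort(names(g)), sort(sprintf("S%03d", 1:200)))
  expect_true(all(g[order(means)] == rep(1:4, each = 50)))
})

test_that("regional curve fitting recovers degenerate and synthetic-truth cohorts", {
  ## identical trees: curve equals the (smoothed) common series
  w <- 2 * exp(-0.03 * (1:80)) + 0.2
  idset <- ring_set(lapply(1:5, function(i)
    ring_series(paste0("T", i), 1930, w, pith_present = TRUE)))
  cv <- fit_regional_curve(idset)
  expect_equal(cv$expected_width[5:76] / w[5:76], rep(1, 72), tolerance = 0.01)
  expect_equal(cv$expected_width[c(1, 80)] / w[c(1, 80)], c(1, 1), tolerance = 0.01)
  ## single tree: curve = smoothed tree
  one <- fit_regional_curve(idset[1])
  expect_equal(one$expected_width[10:70], w[10:70], tolerance = 0.02)
  ## synthetic cohort with known age trend (flat year signal, 5% noise)
  cfg <- flat_config(seed = 5, n = 100L, sigma = 0.05,
                     age_trend = list(alpha_meanlog = log(2), alpha_sdlog = 0,
                                      beta = 0.03, kappa = 0.2))
  coh <- generate_cohort(cfg)
  cv2 <- fit_regional_curve(coh$series)
  ages <- which(cv2$n_per_age >= 20)
  truth <- 2 * exp(-0.03 * ages) + 0.2
  rel_rmse <- sqrt(mean((cv2$expected_width[ages] / truth - 1)^2))
  expect_lt(rel_rmse, 0.05)
  ## negative-exponential alternative recovers the same truth
  cv3 <- fit_regional_curve(coh$series, smoothing = "negexp")
  rel3 <- sqrt(mean((cv3$expected_width[ages] / truth - 1)^2))
  expect_lt(rel3, 0.05)
})

test_that("ratio indices are observed over expected with support checking", {
  cv <- structure(list(group_id = 1L, ages = 1:10,
                       expected_width = c(rep(0.4, 9), 0.001),
                       n_per_age = rep(2L, 10)), class = "regional_curve")
  s <- ring_series("R", 2000, c(0.6, 0.4, 0.002), pith_present = TRUE)
  expect_equal(unname(ratio_indices(s, cv)[1:2]), c(1.5, 1.0))
  s10 <- ring_series("R", 2000, rep(0.4, 10), pith_present = TRUE)
  expect_equal(unname(ratio_indices(s10, cv)[10]), 0.4 / 0.001)
  long <- ring_series("L", 2000, rep(0.4, 11), pith_present = TRUE)
  expect_error(ratio_indices(long, cv), "L.*beyond curve support")
})

test_that("chronologies are biweight means with truncation, bootstrap band and unit mean", {
  idx <- lapply(1:5, function(i) setNames(rep(c(0.8, 1.2), 25), 1901:1950))
  names(idx) <- paste0("T", 1:5)
  ch <- build_chronology(idx, truncation_n = 5L, n_boot = 200L, seed = 1)
  expect_equal(mean(ch$index), 1, tolerance = 1e-9)
  expect_equal(unique(ch$depth), 5L)
  expect_equal(ch$ci_high - ch$ci_low, rep(0, 50))  # identical trees: zero width
  ## single tree, truncation 1: the tree's own indices rescaled
  one <- list(T1 = setNames(seq(0.5, 1.5, length.out = 21), 1980:2000))
  ch1 <- build_chronology(one, truncation_n = 1L, n_boot = 0L)
  expect_equal(ch1$index, as.numeric(one$T1) / mean(one$T1))
  ## truncation trims shallow ends
  ragged <- c(idx, list(T6 = setNames(rep(1, 60), 1891:1950)))
  ch2 <- build_chronology(ragged, truncation_n = 6L, n_boot = 0L)
  expect_identical(range(ch2$year), c(1901L, 1950L))
  expect_warning(build_chronology(one, truncation_n = 3L, n_boot = 0L),
                 "no year reaches")
})

test_that("signal-free RCS converges on flat truth and is a near fixed point", {
  coh <- generate_cohort(flat_config(seed = 3))
  fit <- signal_free_rcs(coh$series, n_boot = 0L)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 3L)
  expect_lt(max(abs(fit$chronology$index - 1)), 0.05)
  expect_equal(mean(fit$chronology$index), 1, tolerance = 1e-9)
  ## idempotence at the fixed point: one more pass moves the chronology
  ## by less than the convergence tolerance
  expect_lt(tail(c(0, fit$deltas), 1L), 0.002)
})

test_that("signal-free RCS recovers a mid-record bump that single-pass shrinks", {
  ## Gaussian bump centred on 1940 injected into an otherwise flat truth
  cfg <- flat_config(seed = 9, n = 100L, sigma = 0.15)
  coh <- generate_cohort(cfg)
  yrs_all <- cfg$years
  bump <- 1 + 0.35 * exp(-((yrs_all - 1940) / 12)^2)
  bump <- bump / mean(bump)
  names(bump) <- yrs_all
  rs <- ring_set(lapply(coh$series, function(s) {
    s$widths <- s$widths * bump[as.character(series_years(s))]
    s
  }))
  suppressWarnings({
    sf <- signal_free_rcs(rs, n_boot = 0L)
    sp <- signal_free_rcs(rs, n_boot = 0L, signal_free = FALSE)
  })
  truth_amp <- max(bump) - 1
  amp_of <- function(ch) {
    tr <- bump[as.character(ch$year)]
    max(ch$index[abs(ch$year - 1940) <= 15]) - 1
  }
  sf_err <- abs(amp_of(sf$chronology) - truth_amp) / truth_amp
  sp_err <- abs(amp_of(sp$chronology) - truth_amp) / truth_amp
  expect_lt(sf_err, 0.15)
  expect_gt(sp_err, sf_err)
})

test_that("subgroup chronologies honour the minimum-tree rule and match scenarios", {
  ## mixed-age recruitment keeps a late-century level shift identifiable
  ## against the age curves
  coh <- generate_cohort(flat_config(seed = 21, n = 60L,
                                     germination_span = 1864:1964))
  rs <- coh$series
  ## predicate selecting everything reproduces the global chronology
  all_fit <- suppressWarnings(
    subgroup_chronology(rs, function(s) TRUE, truncation_n = 50L, n_boot = 0L))
  glob <- suppressWarnings(signal_free_rcs(rs, truncation_n = 50L, n_boot = 0L))
  expect_equal(all_fit$chronology$index, glob$chronology$index, tolerance = 1e-12)
  expect_error(subgroup_chronology(rs, character(0)), "0 trees")
  ## a 1.2x post-1970 growth divergence between two halves shows up in the
  ## subgroup chronologies' recent means
  ids <- names(rs)
  half_b <- ids[31:60]
  rs2 <- ring_set(lapply(rs, function(s) {
    if (s$series_id %in% half_b) {
      yrs <- series_years(s)
      s$widths[yrs >= 1970] <- s$widths[yrs >= 1970] * 1.2
    }
    s
  }))
  suppressWarnings({
    fa <- subgroup_chronology(rs2, ids[1:30], n_boot = 0L)
    fb <- subgroup_chronology(rs2, half_b, n_boot = 0L)
  })
  post <- function(f) mean(f$chronology$index[f$chronology$year >= 1975])
  pre <- function(f) mean(f$chronology$index[f$chronology$year < 1965])
  ratio <- (post(fb) / pre(fb)) / (post(fa) / pre(fa))
  expect_equal(ratio, 1.2, tolerance = 0.05)
})

test_that("chronology CSV round-trips", {
  coh <- small_cohort()
  fit <- suppressWarnings(signal_free_rcs(coh$series, truncation_n = 25L, n_boot = 0L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_chronology(fit$chronology, f)
  back <- read_chronology(f)
  expect_equal(back$index, fit$chronology$index)
  expect_s3_class(back, "chronology")
})
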