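## Multi-curve signal-free RCS detrending and chronology construction.

#' Assign series to RCS growth-rate groups
#'
#' Multi-curve RCS fits a separate age curve to each growth-rate class.
#' Series are ranked by mean ring width and split into contiguous,
#' near-equal-size groups. If any group would contain \code{min_per_group}
#' series or fewer, the number of groups is reduced until every group
#' exceeds \code{min_per_group} (degenerating to single-curve RCS).
#'
#' The growth-rate metric is the mean ring width over a common juvenile
#' cambial-age band (default ages 1-40). Ranking trees by whole-life mean
#' width instead conflates growth rate with age structure -- older trees
#' carry more narrow old-age rings, so the oldest ages of each group are
#' then populated only by its fastest growers, biasing the upper end of
#' the regional curve and destabilizing the signal-free iteration. A
#' common-age band compares like with like.
#'
#' @param series_set A \code{ring_set}.
#' @param n_groups Requested number of curves (default 4, "four-curve RCS").
#' @param min_per_group Minimum series per group that must be exceeded
#'   (default 40).
#' @param rank_age_band Cambial-age band over which the ranking mean width
#'   is computed (default 40 years; series shorter than the band use all
#'   their rings).
#' @return Integer group labels (1 = slowest-growing), named by series id.
#' @export
assign_rcs_groups <- function(series_set, n_groups = 4L, min_per_group = 40L,
                              rank_age_band = 40L) {
  n <- length(series_set)
  if (n == 0L) stop_br("assign_rcs_groups: empty series set")
  if (n_groups < 1L) stop_br("assign_rcs_groups: n_groups must be >= 1")
  k <- as.integer(n_groups)
  while (k > 1L && floor(n / k) <= min_per_group) k <- k - 1L
  mw <- vapply(series_set, function(s) {
    a <- cambial_ages(s)
    sel <- a <= rank_age_band
    mean(if (any(sel)) s$widths[sel] else s$widths)
  }, numeric(1L))
  rank_order <- order(mw)  # ties broken by position: a strict partition
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- integer(n)
  labels[rank_order] <- rep(seq_len(k), times = sizes)
  setNames(labels, names(series_set))
}

#' Fit a regional curve (expected ring width by cambial age)
#'
#' Widths are aligned by cambial age (including estimated missing rings),
#' summarized per age by the biweight mean, and smoothed. The default
#' smoother is the penalized cubic smoothing spline with 50% frequency
#' cutoff at 10% of the maximum cambial age; a modified negative
#' exponential \eqn{w(a) = \alpha e^{-\beta a} + \kappa} is available as an
#' alternative. The curve is floored at 0.001 mm so ratio indices stay
#' defined.
#'
#' @param group_set A \code{ring_set} (one RCS group).
#' @param smoothing \code{"spline"} or \code{"negexp"}.
#' @param cutoff_frac Spline cutoff as a fraction of the maximum cambial age.
#' @param floor_mm Lower bound on the expected width.
#' @param widths_override Optional named list replacing each series' widths
#'   (used by the signal-free iteration, which refits curves from
#'   signal-free measurements).
#' @param group_id Integer label stored on the curve.
#' @return A \code{regional_curve}: list with \code{ages},
#'   \code{expected_width}, \code{n_per_age}, \code{group_id}.
#' @export
fit_regional_curve <- function(group_set, smoothing = c("spline", "negexp"),
                               cutoff_frac = 0.1, floor_mm = 0.001,
                               widths_override = NULL, group_id = 1L) {
  smoothing <- match.arg(smoothing)
  if (length(group_set) == 0L) stop_br("fit_regional_curve: empty group")
  ages <- integer(0); w <- numeric(0)
  for (s in group_set) {
    wi <- if (is.null(widths_override)) s$widths else widths_override[[s$series_id]]
    ages <- c(ages, cambial_ages(s))
    w <- c(w, wi)
  }
  a_max <- max(ages)
  n_per_age <- tabulate(ages, nbins = a_max)
  raw <- rep(NA_real_, a_max)
  by_age <- split(w, ages)
  raw[as.integer(names(by_age))] <-
    vapply(by_age, biweight_mean, numeric(1L))
  if (all(!is.finite(raw) | raw == 0))
    stop_br("fit_regional_curve: no usable (non-zero) age column")
  expected <- switch(smoothing,
    spline = spline_smooth(raw, cutoff = max(3, cutoff_frac * a_max)),
    negexp = {
      ok <- which(!is.na(raw))
      df <- data.frame(a = ok, y = raw[ok])
      fit <- tryCatch(
        nls(y ~ alpha * exp(-beta * a) + kappa, data = df,
            start = list(alpha = max(df$y) - min(df$y) + 1e-3,
                         beta = 0.02, kappa = max(min(df$y), 1e-3)),
            control = list(maxiter = 200, warnOnly = TRUE)),
        error = function(e) NULL)
      if (is.null(fit)) {
        spline_smooth(raw, cutoff = max(3, cutoff_frac * a_max))
      } else {
        out <- rep(NA_real_, a_max)
        out[which(n_per_age > 0)] <- predict(fit, newdata = list(a = which(n_per_age > 0)))
        out
      }
    })
  expected[!is.na(expected) & expected < floor_mm] <- floor_mm
  expected[n_per_age == 0L] <- NA_real_
  structure(list(group_id = as.integer(group_id), ages = seq_len(a_max),
                 expected_width = expected, n_per_age = n_per_age),
            class = "regional_curve")
}

#' @export
print.regional_curve <- function(x, ...) {
  cat(sprintf("<regional_curve> group %d, ages 1-%d, max depth %d\n",
              x$group_id, length(x$ages), max(x$n_per_age)))
  invisible(x)
}

#' Ring-width indices as ratios of observed to expected growth
#'
#' @param series A \code{ring_series}.
#' @param curve A \code{regional_curve} covering every cambial age the
#'   series uses.
#' @return Named numeric vector of dimensionless indices, names = calendar
#'   years.
#' @export
ratio_indices <- function(series, curve) {
  ages <- cambial_ages(series)
  bad <- ages > length(curve$ages) | is.na(curve$expected_width[ages])
  if (any(bad))
    stop_br("ratio_indices: series '", series$series_id,
            "' has age(s) beyond curve support: ",
            paste(head(ages[bad], 3L), collapse = ", "))
  setNames(series$widths / curve$expected_width[ages], series_years(series))
}

## Assemble per-series index vectors (named by year) into a years x trees
## matrix over the union of years.
index_matrix <- function(index_list) {
  yrs <- sort(unique(unlist(lapply(index_list, function(v) as.integer(names(v))))))
  M <- matrix(NA_real_, length(yrs), length(index_list),
              dimnames = list(yrs, names(index_list)))
  for (j in seq_along(index_list)) {
    v <- index_list[[j]]
    M[match(as.integer(names(v)), yrs), j] <- v
  }
  M
}

#' Build a chronology from ring-width indices
#'
#' Per-year biweight mean across trees, truncated where the sample depth
#' drops below \code{truncation_n} at either end, with a percentile
#' bootstrap 95% band (resampling trees within each year) and a final
#' multiplicative rescale so the retained-span mean is exactly 1.
#'
#' Interior years below the depth threshold (possible with fire-filtered
#' series) are retained and flagged in the \code{"interior_below_threshold"}
#' attribute.
#'
#' @param ind Either a years x trees index matrix (rownames = years) or a
#'   named list of per-series index vectors.
#' @param truncation_n Minimum sample depth (default 50 trees).
#' @param n_boot Bootstrap replicates for the 95% band (default 1000); 0
#'   skips the band.
#' @param seed Optional RNG seed for the bootstrap.
#' @return A \code{chronology}: data frame with \code{year}, \code{index},
#'   \code{depth}, \code{ci_low}, \code{ci_high}.
#' @export
build_chronology <- function(ind, truncation_n = 50L, n_boot = 1000L,
                             seed = NULL) {
  if (is.list(ind)) ind <- index_matrix(ind)
  yrs <- as.integer(rownames(ind))
  depth <- rowSums(is.finite(ind))
  idx <- vapply(seq_len(nrow(ind)), function(i) {
    v <- ind[i, ]; v <- v[is.finite(v)]
    if (length(v) == 0L) NA_real_ else biweight_mean(v)
  }, numeric(1L))
  ok <- which(depth >= truncation_n)
  if (length(ok) == 0L) {
    warning("build_chronology: no year reaches sample depth ", truncation_n,
            call. = FALSE)
    out <- data.frame(year = integer(0), index = numeric(0), depth = integer(0),
                      ci_low = numeric(0), ci_high = numeric(0))
    return(structure(out, class = c("chronology", "data.frame"),
                     truncation_n = truncation_n))
  }
  keep <- seq(min(ok), max(ok))
  interior_low <- yrs[keep][depth[keep] < truncation_n]
  ci_low <- ci_high <- rep(NA_real_, length(keep))
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    for (k in seq_along(keep)) {
      v <- ind[keep[k], ]; v <- v[is.finite(v)]
      if (length(v) < 2L) next
      bm <- vapply(seq_len(n_boot), function(b)
        biweight_mean(v[sample.int(length(v), replace = TRUE)]), numeric(1L))
      qs <- quantile(bm, c(0.025, 0.975), names = FALSE)
      ci_low[k] <- qs[1L]; ci_high[k] <- qs[2L]
    }
  }
  scale <- mean(idx[keep])
  out <- data.frame(year = yrs[keep], index = idx[keep] / scale,
                    depth = as.integer(depth[keep]),
                    ci_low = ci_low / scale, ci_high = ci_high / scale)
  structure(out, class = c("chronology", "data.frame"),
            truncation_n = truncation_n,
            interior_below_threshold = interior_low)
}

#' @export
print.chronology <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<chronology> empty\n")
    return(invisible(x))
  }
  cat(sprintf("<chronology> %d-%d (%d yr), depth %d-%d, mean %.6f\n",
              min(x$year), max(x$year), nrow(x), min(x$depth), max(x$depth),
              mean(x$index)))
  invisible(x)
}

#' @export
plot.chronology <- function(x, ...) {
  plot(x$year, x$index, type = "n", xlab = "Year", ylab = "Ring-width index",
       ylim = range(c(x$index, x$ci_low, x$ci_high), na.rm = TRUE), ...)
  if (any(is.finite(x$ci_low)))
    graphics::polygon(c(x$year, rev(x$year)), c(x$ci_low, rev(x$ci_high)),
                      col = "grey85", border = NA)
  graphics::lines(x$year, x$index)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

## Full-span (untruncated, no CI) chronology used inside the signal-free
## iteration; rescaled to mean 1 so measurement scale is preserved.
chronology_full <- function(ind_mat) {
  idx <- vapply(seq_len(nrow(ind_mat)), function(i) {
    v <- ind_mat[i, ]; v <- v[is.finite(v)]
    if (length(v) == 0L) NA_real_ else biweight_mean(v)
  }, numeric(1L))
  idx / mean(idx, na.rm = TRUE)
}

#' Signal-free multi-curve RCS detrending
#'
#' Iterative RCS: (1) fit regional curves and a chronology from the current
#' measurements; (2) divide each raw width by that year's chronology index
#' to form signal-free measurements; (3) refit the curves from the
#' signal-free measurements and recompute indices and the chronology from
#' the raw widths against the refit curves. Iteration stops when the
#' maximum per-year absolute change in the chronology is below \code{tol}
#' or after \code{max_iter} iterations (with a warning), keeping the
#' iteration count below ten. Removing the common year signal before curve
#' fitting corrects the inadvertent absorption of climate signal into the
#' age curve that biases single-pass RCS.
#'
#' @param series_set A \code{ring_set} of dated, pith-corrected series.
#' @param n_groups Requested number of RCS curves (default 4).
#' @param max_iter Iteration cap (default 9).
#' @param tol Convergence tolerance on the per-year chronology change
#'   (default 0.002).
#' @param truncation_n Sample-depth truncation for the returned chronology
#'   (default 50).
#' @param n_boot,seed Bootstrap settings for the chronology band.
#' @param smoothing Curve smoother, see \code{\link{fit_regional_curve}}.
#' @param signal_free If \code{FALSE}, performs single-pass RCS (one
#'   iteration, no signal removal).
#' @return A \code{signal_free_rcs} list: \code{chronology},
#'   \code{curves}, \code{groups}, \code{indices} (years x trees matrix),
#'   \code{iterations}, \code{deltas} (per-iteration max change),
#'   \code{converged}.
#' @export
signal_free_rcs <- function(series_set, n_groups = 4L, max_iter = 9L,
                            tol = 0.002, truncation_n = 50L,
                            n_boot = 1000L, seed = NULL,
                            smoothing = "spline", signal_free = TRUE) {
  if (length(series_set) == 0L) stop_br("signal_free_rcs: empty series set")
  groups <- assign_rcs_groups(series_set, n_groups)
  ids <- names(series_set)
  raw <- lapply(series_set, `[[`, "widths")
  cur <- raw
  prev_idx <- NULL
  deltas <- numeric(0)
  converged <- FALSE
  if (!signal_free) max_iter <- 1L
  for (iter in seq_len(max_iter)) {
    curves <- lapply(sort(unique(groups)), function(g)
      fit_regional_curve(series_set[ids[groups == g]], smoothing = smoothing,
                         widths_override = cur, group_id = g))
    names(curves) <- sort(unique(groups))
    ind <- lapply(ids, function(id)
      ratio_indices(series_set[[id]], curves[[as.character(groups[[id]])]]))
    names(ind) <- ids
    M <- index_matrix(ind)
    chron <- chronology_full(M)
    if (!is.null(prev_idx)) {
      d <- max(abs(chron - prev_idx), na.rm = TRUE)
      deltas <- c(deltas, d)
      if (d < tol) { converged <- TRUE; break }
    }
    prev_idx <- chron
    if (!signal_free) break
    yr_index <- setNames(chron, rownames(M))
    cur <- lapply(ids, function(id) {
      yrs <- as.character(series_years(series_set[[id]]))
      raw[[id]] / yr_index[yrs]
    })
    names(cur) <- ids
  }
  if (signal_free && !converged && max_iter > 1L)
    warning("signal_free_rcs: not converged after ", max_iter,
            " iterations (last max change ", signif(tail(deltas, 1L), 3),
            "); returning last iterate", call. = FALSE)
  chronology <- build_chronology(M, truncation_n = truncation_n,
                                 n_boot = n_boot, seed = seed)
  structure(list(chronology = chronology, curves = curves, groups = groups,
                 indices = M, iterations = if (signal_free) iter else 1L,
                 deltas = deltas, converged = converged || !signal_free),
            class = "signal_free_rcs")
}

#' @export
print.signal_free_rcs <- function(x, ...) {
  cat(sprintf("<signal_free_rcs> %d trees, %d curve(s), %d iteration(s)%s\n",
              ncol(x$indices), length(x$curves), x$iterations,
              if (x$converged) "" else " (not converged)"))
  print(x$chronology)
  invisible(x)
}

#' Chronology for a subset of trees
#'
#' Runs the full signal-free RCS pipeline on a predicate-selected subset
#' (used for plot-type and good/poor-habitat chronologies). Subgroup
#' chronologies use a lower default sample-depth threshold (25 trees).
#'
#' @param series_set A \code{ring_set}.
#' @param predicate A function of a \code{ring_series} returning
#'   \code{TRUE}/\code{FALSE}, a logical vector, or a character vector of
#'   series ids.
#' @param min_n Minimum subset size (default 25 trees).
#' @param truncation_n Sample-depth threshold (default \code{min_n}).
#' @param ... Passed to \code{\link{signal_free_rcs}}.
#' @return A \code{signal_free_rcs} object for the subset.
#' @export
subgroup_chronology <- function(series_set, predicate, min_n = 25L,
                                truncation_n = min_n, ...) {
  sel <- if (is.function(predicate)) {
    vapply(series_set, function(s) isTRUE(predicate(s)), logical(1L))
  } else if (is.character(predicate)) {
    names(series_set) %in% predicate
  } else {
    as.logical(predicate)
  }
  n <- sum(sel)
  if (n < min_n)
    stop_br("subgroup_chronology: subset has ", n,
            " trees, fewer than the required ", min_n)
  signal_free_rcs(series_set[which(sel)], truncation_n = truncation_n, ...)
}

#' Write or read a chronology as CSV
#'
#' @param x A \code{chronology}.
#' @param path CSV path.
#' @return \code{write_chronology}: \code{path} invisibly;
#'   \code{read_chronology}: a \code{chronology}.
#' @export
write_chronology <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chronology
#' @export
read_chronology <- function(path) {
  df <- read.csv(path)
  structure(df, class = c("chronology", "data.frame"))
}
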