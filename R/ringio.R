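## Ring-width series objects and Tucson/RWL input-output.

#' Construct a single tree-ring series
#'
#' A \code{ring_series} holds one tree's dated ring widths together with the
#' pith-correction metadata needed for cambial-age alignment in RCS
#' detrending. The cambial age of the ring formed in year \code{y} is
#' \code{(y - first_year + 1) + missing_rings}.
#'
#' @param series_id,tree_id,plot_id Identifiers (characters). \code{tree_id}
#'   and \code{plot_id} default to \code{series_id} and its prefix.
#' @param species \code{"black_spruce"} or \code{"white_spruce"}.
#' @param plot_type \code{"FIA"} or \code{"AIRIS"}.
#' @param first_year Calendar year (CE) of the innermost measured ring.
#' @param widths Numeric vector of ring widths in mm, one per consecutive
#'   year, all non-negative.
#' @param pith_present Logical; if \code{TRUE}, missing radius and missing
#'   rings are forced to zero.
#' @param missing_radius_mm,missing_rings Pith-offset estimates (see
#'   \code{\link{estimate_missing_radius}}).
#' @param fire_year Calendar year of a known fire at the plot, or \code{NA}.
#' @return An object of class \code{ring_series}.
#' @export
ring_series <- function(series_id, first_year, widths,
                        tree_id = series_id, plot_id = series_id,
                        species = c("black_spruce", "white_spruce"),
                        plot_type = c("FIA", "AIRIS"),
                        pith_present = FALSE,
                        missing_radius_mm = NA_real_,
                        missing_rings = NA_integer_,
                        fire_year = NA_integer_) {
  species <- match.arg(species)
  plot_type <- match.arg(plot_type)
  widths <- as.numeric(widths)
  if (length(widths) < 1L) stop_br("ring_series: at least one ring required")
  if (any(!is.finite(widths)) || any(widths < 0))
    stop_br("ring_series '", series_id, "': widths must be finite and >= 0")
  if (isTRUE(pith_present)) {
    missing_radius_mm <- 0
    missing_rings <- 0L
  }
  x <- structure(list(
    series_id = as.character(series_id),
    tree_id = as.character(tree_id),
    plot_id = as.character(plot_id),
    species = species,
    plot_type = plot_type,
    first_year = as.integer(first_year),
    widths = widths,
    pith_present = isTRUE(pith_present),
    missing_radius_mm = as.numeric(missing_radius_mm),
    missing_rings = as.integer(missing_rings),
    fire_year = as.integer(fire_year)
  ), class = "ring_series")
  x
}

#' @export
print.ring_series <- function(x, ...) {
  yrs <- series_years(x)
  cat(sprintf("<ring_series> %s (%s, %s) %d-%d, %d rings%s\n",
              x$series_id, x$species, x$plot_type,
              min(yrs), max(yrs), length(x$widths),
              if (isTRUE(x$pith_present)) ", pith" else
                sprintf(", +%s missing rings",
                        ifelse(is.na(x$missing_rings), "?", x$missing_rings))))
  invisible(x)
}

#' Years and cambial ages of a ring series
#'
#' @param x A \code{ring_series}.
#' @return \code{series_years}: the calendar years; \code{cambial_ages}: the
#'   ring ages counted from the pith, including the estimated missing rings.
#' @export
series_years <- function(x) x$first_year + seq_along(x$widths) - 1L

#' @rdname series_years
#' @export
cambial_ages <- function(x) {
  off <- x$missing_rings
  if (is.na(off)) off <- 0L
  seq_along(x$widths) + off
}

#' Collect ring series into a set
#'
#' @param ... \code{ring_series} objects or a single list of them.
#' @return A \code{ring_set}: a named list of \code{ring_series}.
#' @export
ring_set <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1L]], "ring_series")) xs <- xs[[1L]]
  ok <- vapply(xs, inherits, logical(1L), "ring_series")
  if (!all(ok)) stop_br("ring_set: all elements must be ring_series")
  ids <- vapply(xs, `[[`, character(1L), "series_id")
  if (anyDuplicated(ids)) stop_br("ring_set: duplicate series ids: ",
                                  paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(setNames(xs, ids), class = "ring_set")
}

#' @export
print.ring_set <- function(x, ...) {
  yrs <- range(unlist(lapply(x, series_years)))
  cat(sprintf("<ring_set> %d series, %d-%d\n", length(x), yrs[1L], yrs[2L]))
  invisible(x)
}

#' @export
`[.ring_set` <- function(x, i) {
  structure(NextMethod(), class = "ring_set")
}

#' Read a Tucson/RWL decadal ring-width file
#'
#' Parses the decadal layout (one line per series and decade: series id,
#' first year of the line, then up to ten values). The stop marker at the
#' end of each series selects the unit dialect: \code{999} means values are
#' in 0.01 mm, \code{-9999} means 0.001 mm. Widths are returned in mm.
#'
#' @param path Path to an RWL file.
#' @return A \code{ring_set} (series metadata beyond id/years must be joined
#'   from a metadata table, see \code{\link{load_ring_data}}).
#' @export
read_rwl <- function(path) {
  if (!file.exists(path)) stop_br("read_rwl: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  recs <- list()
  for (k in seq_along(lines)) {
    toks <- strsplit(trimws(lines[k]), "[ \t]+")[[1L]]
    if (length(toks) < 3L)
      stop_br("read_rwl: malformed decade line ", lineno[k], ": '", lines[k], "'")
    id <- toks[1L]
    year <- suppressWarnings(as.integer(toks[2L]))
    vals <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (is.na(year) || anyNA(vals))
      stop_br("read_rwl: malformed decade line ", lineno[k], ": '", lines[k], "'")
    recs[[k]] <- list(id = id, year = year, vals = vals)
  }
  ids <- vapply(recs, `[[`, character(1L), "id")
  out <- list()
  for (id in unique(ids)) {
    rr <- recs[ids == id]
    years <- vapply(rr, `[[`, integer(1L), "year")
    rr <- rr[order(years)]
    years <- sort(years)
    vals <- integer(0)
    yr0 <- rr[[1L]]$year
    expect <- yr0
    raw <- numeric(0)
    for (r in rr) {
      if (r$year < expect)
        stop_br("read_rwl: overlapping decade lines for duplicate series id '", id, "'")
      if (r$year > expect && length(raw) > 0L)
        stop_br("read_rwl: gap in decade lines for series '", id, "'")
      raw <- c(raw, r$vals)
      expect <- r$year + length(r$vals)
    }
    ## The stop marker is the terminal value of the series and selects the
    ## unit dialect; an interior 999 in the -9999 dialect is a real 0.999 mm.
    last <- raw[length(raw)]
    if (last == -9999) {
      scale <- 0.001
      raw <- raw[-length(raw)]
    } else if (last == 999) {
      scale <- 0.01
      raw <- raw[-length(raw)]
    } else {
      scale <- 0.001  # unterminated series: assume the high-precision dialect
    }
    if (length(raw) < 1L)
      stop_br("read_rwl: series '", id, "' has no measurements before its stop marker")
    if (any(raw < 0))
      stop_br("read_rwl: negative width in series '", id, "'")
    out[[id]] <- ring_series(series_id = id, first_year = yr0, widths = raw * scale)
  }
  br_log("read_rwl: ", length(out), " series from ", path)
  ring_set(out)
}

#' Write a Tucson/RWL decadal ring-width file
#'
#' @param x A \code{ring_set}.
#' @param path Output path.
#' @param precision Measurement precision in mm: \code{0.001} (stop marker
#'   \code{-9999}, the bench-micrometer dialect) or \code{0.01} (marker
#'   \code{999}).
#' @return \code{path}, invisibly. \code{read_rwl(write_rwl(x))} round-trips
#'   widths and years exactly at the chosen precision.
#' @export
write_rwl <- function(x, path, precision = 0.001) {
  if (!precision %in% c(0.001, 0.01)) stop_br("write_rwl: precision must be 0.001 or 0.01")
  marker <- if (precision == 0.001) -9999L else 999L
  con <- file(path, "w")
  on.exit(close(con))
  for (s in x) {
    yrs <- series_years(s)
    vals <- as.integer(round(s$widths / precision))
    vals <- c(vals, marker)
    vyrs <- c(yrs, max(yrs) + 1L)
    dec <- vyrs %/% 10L
    for (d in unique(dec)) {
      sel <- dec == d
      cat(sprintf("%-8s %4d%s", substr(s$series_id, 1L, 8L), min(vyrs[sel]),
                  paste(sprintf("%6d", vals[sel]), collapse = "")),
          file = con, sep = "\n")
    }
  }
  br_log("write_rwl: ", length(x), " series to ", path)
  invisible(path)
}

#' Estimate the missing radius from an innermost complete arc
#'
#' For cores that missed the pith but passed close enough for the innermost
#' measured ring to form a complete arc, the geometric method recovers the
#' distance to the pith as the radius of the circle through the arc:
#' \deqn{r = \mathrm{chord}^2 / (8\,\mathrm{height}) + \mathrm{height}/2.}
#'
#' @param chord_mm Chord across the innermost complete arc (mm, > 0).
#' @param height_mm Arc height from chord to arc (mm, > 0); must not exceed
#'   the chord (flat-to-semicircular arcs).
#' @return Missing radius in mm.
#' @examples
#' estimate_missing_radius(20, 2)  # 26 mm
#' @export
estimate_missing_radius <- function(chord_mm, height_mm) {
  if (any(!is.finite(chord_mm)) || any(!is.finite(height_mm)) ||
      any(chord_mm <= 0) || any(height_mm <= 0))
    stop_br("estimate_missing_radius: chord and height must be positive")
  if (any(height_mm > chord_mm))
    stop_br("estimate_missing_radius: arc height exceeds chord (not a flat arc)")
  chord_mm^2 / (8 * height_mm) + height_mm / 2
}

#' Estimate the number of missing rings
#'
#' Divides the mean width of the first ten measured rings into the missing
#' radius; the count is rounded half-to-even (the banker's rounding R
#' applies).
#'
#' @param series A \code{ring_series} with at least ten rings.
#' @param missing_radius Missing radius in mm (>= 0).
#' @return The input series with \code{missing_radius_mm} and
#'   \code{missing_rings} set.
#' @export
estimate_missing_rings <- function(series, missing_radius) {
  if (!is.finite(missing_radius) || missing_radius < 0)
    stop_br("estimate_missing_rings: missing_radius must be >= 0")
  if (length(series$widths) < 10L)
    stop_br("estimate_missing_rings: series '", series$series_id,
            "' has fewer than 10 rings")
  m <- mean(series$widths[1:10])
  if (m <= 0) stop_br("estimate_missing_rings: zero mean width in first 10 rings")
  series$missing_radius_mm <- missing_radius
  series$missing_rings <- as.integer(round(missing_radius / m))
  series
}

#' Remove post-fire rings from a series
#'
#' Plots with a known fire history have all post-fire ring-width data
#' eliminated; by the conservative default the fire year itself is removed
#' too.
#'
#' @param series A \code{ring_series} (its \code{fire_year} may be \code{NA}).
#' @param include_fire_year If \code{TRUE} (default) the fire year is removed
#'   along with all later years.
#' @return The truncated series, or \code{NULL} (with a warning) if nothing
#'   pre-fire remains.
#' @export
apply_fire_filter <- function(series, include_fire_year = TRUE) {
  fy <- series$fire_year
  if (is.na(fy)) return(series)
  yrs <- series_years(series)
  cut <- if (include_fire_year) fy else fy + 1L
  keep <- yrs < cut
  if (!any(keep)) {
    warning("apply_fire_filter: series '", series$series_id,
            "' entirely post-fire; dropped", call. = FALSE)
    return(NULL)
  }
  if (all(keep)) return(series)
  series$widths <- series$widths[keep]
  series
}

#' Read a per-tree metadata table
#'
#' Expected columns: \code{series_id}, \code{tree_id}, \code{plot_id},
#' \code{species}, \code{plot_type}, \code{pith_present}, and optionally
#' \code{chord_mm}, \code{height_mm} (innermost-arc measurements) and
#' \code{fire_year}.
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_tree_metadata <- function(path) {
  if (!file.exists(path)) stop_br("read_tree_metadata: file not found: ", path)
  meta <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("series_id", "species", "plot_type", "pith_present")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop_br("read_tree_metadata: missing columns: ",
                            paste(miss, collapse = ", "))
  br_log("read_tree_metadata: ", nrow(meta), " rows from ", path)
  meta
}

#' Load ring widths plus metadata and apply pith and fire corrections
#'
#' Joins an RWL file with its metadata table, estimates missing radius and
#' ring counts for cores lacking the pith (from arc chord/height), drops
#' series that have neither pith nor a usable arc, and applies the fire
#' filter.
#'
#' @param rwl_path RWL file path.
#' @param meta_path Metadata CSV path (see \code{\link{read_tree_metadata}}).
#' @param include_fire_year Passed to \code{\link{apply_fire_filter}}.
#' @return A \code{ring_set} of corrected series.
#' @export
load_ring_data <- function(rwl_path, meta_path, include_fire_year = TRUE) {
  rs <- read_rwl(rwl_path)
  meta <- read_tree_metadata(meta_path)
  out <- list()
  dropped <- 0L
  for (id in names(rs)) {
    s <- rs[[id]]
    row <- meta[meta$series_id == id, , drop = FALSE]
    if (nrow(row) != 1L) {
      warning("load_ring_data: no unique metadata row for '", id, "'; dropped",
              call. = FALSE)
      dropped <- dropped + 1L
      next
    }
    s <- ring_series(series_id = id,
                     tree_id = row$tree_id %||% id,
                     plot_id = row$plot_id %||% id,
                     species = row$species, plot_type = row$plot_type,
                     first_year = s$first_year, widths = s$widths,
                     pith_present = isTRUE(row$pith_present) || row$pith_present == "TRUE",
                     fire_year = if ("fire_year" %in% names(row)) row$fire_year else NA)
    if (!s$pith_present) {
      ch <- if ("chord_mm" %in% names(row)) row$chord_mm else NA
      ht <- if ("height_mm" %in% names(row)) row$height_mm else NA
      if (is.na(ch) || is.na(ht) || length(s$widths) < 10L) {
        br_log("load_ring_data: '", id, "' lacks pith and usable arc; excluded")
        dropped <- dropped + 1L
        next
      }
      s <- estimate_missing_rings(s, estimate_missing_radius(ch, ht))
    }
    s <- apply_fire_filter(s, include_fire_year)
    if (is.null(s)) { dropped <- dropped + 1L; next }
    out[[id]] <- s
  }
  br_log("load_ring_data: kept ", length(out), " series, dropped ", dropped)
  ring_set(out)
}

#' Simplified inter-series correlation quality control
#'
#' Each series is high-pass filtered (ratio to a smoothing spline with 50%
#' frequency cutoff \code{detrend_window}) and correlated against the
#' biweight mean of all other filtered series over their overlap. This is a
#' screening statistic in the spirit of crossdating programs, not a full
#' segment-by-segment diagnostic.
#'
#' @param series_set A \code{ring_set} with at least two series.
#' @param detrend_window Spline cutoff in years (default 32).
#' @param min_overlap Minimum pairwise overlap in years (default 20).
#' @return A list with \code{r} (named per-series correlations, \code{NA}
#'   when flagged for insufficient overlap), \code{mean_r} (arithmetic mean
#'   over unflagged series) and \code{flagged} (series ids).
#' @export
interseries_correlation <- function(series_set, detrend_window = 32,
                                    min_overlap = 20) {
  if (length(series_set) < 2L)
    stop_br("interseries_correlation: need at least two series")
  yrs <- lapply(series_set, series_years)
  all_years <- seq(min(unlist(yrs)), max(unlist(yrs)))
  M <- matrix(NA_real_, length(all_years), length(series_set),
              dimnames = list(all_years, names(series_set)))
  for (j in seq_along(series_set)) {
    s <- series_set[[j]]
    M[match(series_years(s), all_years), j] <-
      highpass_ratio(s$widths, detrend_window)
  }
  r <- setNames(rep(NA_real_, ncol(M)), colnames(M))
  for (j in seq_len(ncol(M))) {
    others <- M[, -j, drop = FALSE]
    ref <- apply(others, 1L, function(v) {
      v <- v[is.finite(v)]
      if (length(v) == 0L) NA_real_ else biweight_mean(v)
    })
    ok <- is.finite(M[, j]) & is.finite(ref)
    if (sum(ok) >= min_overlap && sd(M[ok, j]) > 0 && sd(ref[ok]) > 0)
      r[j] <- cor(M[ok, j], ref[ok])
  }
  flagged <- names(r)[is.na(r)]
  if (length(flagged))
    br_log("interseries_correlation: flagged (insufficient overlap): ",
           paste(flagged, collapse = ", "))
  list(r = r, mean_r = mean(r, na.rm = TRUE), flagged = flagged)
}
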