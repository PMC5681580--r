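## Habitat analysis: recent growth vs. plot covariates, good/poor habitat
## classification and habitat-stratified climate sensitivity.

#' Per-tree mean ring-width index over a recent span
#'
#' @param ind Years x trees index matrix (e.g. \code{fit$indices} from
#'   \code{\link{signal_free_rcs}}) or a named list of per-series index
#'   vectors.
#' @param span Years to average over (default 2003:2012).
#' @return Data frame with \code{series_id}, \code{mean_recent_rwi} and
#'   \code{n_years}; trees with no index year in the span are excluded and
#'   logged.
#' @export
recent_mean_rwi <- function(ind, span = 2003:2012) {
  if (is.list(ind)) ind <- index_matrix(ind)
  rows <- rownames(ind) %in% as.character(span)
  sub <- ind[rows, , drop = FALSE]
  n_years <- colSums(is.finite(sub))
  keep <- n_years > 0L
  if (any(!keep))
    br_log("recent_mean_rwi: excluded ", sum(!keep),
           " tree(s) with no index in span: ",
           paste(head(colnames(ind)[!keep], 5L), collapse = ", "))
  data.frame(series_id = colnames(sub)[keep],
             mean_recent_rwi = colMeans(sub[, keep, drop = FALSE], na.rm = TRUE),
             n_years = n_years[keep], row.names = NULL)
}

#' Classify habitat quality for a plot
#'
#' Fixed-threshold rules derived from partial-dependence breakpoints of the
#' habitat BRT analysis. White spruce: good habitat has moss cover below
#' 50\% and duff depth below 10 cm; poor has moss above 50\% and duff
#' deeper than 10 cm. Black spruce: good habitat has slope above 15\% and
#' moss cover above 60\%; poor has slope below 15\% and moss below 60\%.
#' All other combinations, boundary equalities, and records missing a
#' required field are unclassified. Good and poor are mutually exclusive by
#' construction.
#'
#' @param record A one-row data frame or list with \code{moss_cover},
#'   \code{duff_depth} and \code{slope} as needed by the species' rule.
#' @param species \code{"black_spruce"} or \code{"white_spruce"}.
#' @return \code{"good"}, \code{"poor"} or \code{"unclassified"}.
#' @export
classify_habitat <- function(record, species = c("black_spruce", "white_spruce")) {
  species <- match.arg(species)
  get <- function(f) {
    v <- record[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v)) NA_real_ else as.numeric(v)
  }
  if (species == "white_spruce") {
    moss <- get("moss_cover"); duff <- get("duff_depth")
    if (is.na(moss) || is.na(duff)) return("unclassified")
    if (moss < 50 && duff < 10) return("good")
    if (moss > 50 && duff > 10) return("poor")
  } else {
    slope <- get("slope"); moss <- get("moss_cover")
    if (is.na(slope) || is.na(moss)) return("unclassified")
    if (slope > 15 && moss > 60) return("good")
    if (slope < 15 && moss < 60) return("poor")
  }
  "unclassified"
}

#' Boosted regression tree analysis of habitat controls on recent growth
#'
#' Relates per-tree recent mean ring-width index to plot locational and
#' structural covariates (and optionally plot-mean discrimination) with the
#' same BRT engine and settings as the climate model; categorical
#' predictors are one-hot encoded, constant predictors dropped with a
#' warning, and relative influence is normalized to 100.
#'
#' @param records Data frame with \code{mean_recent_rwi} plus any of:
#'   \code{aspect}, \code{basal_area}, \code{delta13c}, \code{duff_depth},
#'   \code{elevation}, \code{litter_depth}, \code{moss_cover},
#'   \code{region}, \code{slope}, \code{stand_age}, \code{stand_density},
#'   \code{topographic_position}, \code{stand_type}.
#' @param predictors Optional explicit predictor columns; default is every
#'   recognized covariate present.
#' @param ... Passed to \code{\link{fit_brt}}.
#' @return A \code{brt_model}.
#' @export
brt_habitat_model <- function(records, predictors = NULL, ...) {
  stopifnot("mean_recent_rwi" %in% names(records))
  known <- c("aspect", "basal_area", "delta13c", "duff_depth", "elevation",
             "litter_depth", "moss_cover", "region", "slope", "stand_age",
             "stand_density", "topographic_position", "stand_type")
  if (is.null(predictors)) predictors <- intersect(known, names(records))
  if (length(predictors) == 0L) stop_br("brt_habitat_model: no predictors found")
  fit_brt(records[, predictors, drop = FALSE], records$mean_recent_rwi, ...)
}

#' Habitat-stratified climate sensitivity
#'
#' Builds good- and poor-habitat chronologies per species (full signal-free
#' RCS on each stratum, 25-tree threshold) and computes static
#' correlations with the sixteen monthly climate variables over the span,
#' returning the species x habitat x variable correlation grid with
#' significance flags. Strata with too few trees are omitted with a
#' warning.
#'
#' @param series_set A \code{ring_set}.
#' @param climvars Output of \code{\link{climate_variables}}.
#' @param classification Named character vector (series id ->
#'   \code{"good"}/\code{"poor"}/\code{"unclassified"}), or a data frame
#'   with \code{series_id} and \code{habitat_class}.
#' @param span Correlation span (default the full overlap).
#' @param min_n Minimum trees per stratum (default 25).
#' @param n_boot,seed Bootstrap settings for significance.
#' @param ... Passed to \code{\link{signal_free_rcs}} via
#'   \code{\link{subgroup_chronology}}.
#' @return List: \code{table} (long data frame: species, habitat_class,
#'   variable, r, significant), \code{chronologies} (named list of
#'   \code{signal_free_rcs} fits).
#' @export
stratified_climate_sensitivity <- function(series_set, climvars, classification,
                                           span = NULL, min_n = 25L,
                                           n_boot = 1000L, seed = NULL, ...) {
  if (is.data.frame(classification))
    classification <- setNames(as.character(classification$habitat_class),
                               classification$series_id)
  species <- vapply(series_set, `[[`, character(1L), "species")
  cls <- classification[names(series_set)]
  out <- list(); chrons <- list()
  for (sp in sort(unique(species))) {
    for (hc in c("good", "poor")) {
      ids <- names(series_set)[species == sp & !is.na(cls) & cls == hc]
      if (length(ids) < min_n) {
        warning("stratified_climate_sensitivity: ", sp, "/", hc, " stratum has ",
                length(ids), " trees (< ", min_n, "); omitted", call. = FALSE)
        next
      }
      fit <- subgroup_chronology(series_set, ids, min_n = min_n,
                                 n_boot = 0L, seed = seed, ...)
      chrons[[paste(sp, hc, sep = ".")]] <- fit
      info <- attr(climvars, "var_info")
      sc <- static_correlations(fit$chronology, climvars, span = span,
                                n_boot = n_boot, seed = seed)
      sc <- sc[sc$variable %in% info$variable[info$monthly], ]
      out[[paste(sp, hc, sep = ".")]] <-
        data.frame(species = sp, habitat_class = hc, sc, row.names = NULL)
    }
  }
  list(table = do.call(rbind, c(out, list(make.row.names = FALSE))),
       chronologies = chrons)
}
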