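## Tree-ring carbon-isotope gas-exchange physiology: discrimination,
## ring-age adjustment, Ci/Ca, Ci and intrinsic water-use efficiency.

#' Carbon isotope discrimination
#'
#' \deqn{\Delta^{13}C = (\delta^{13}C_a - \delta^{13}C_{tree}) /
#'   (1 + \delta^{13}C_{tree}/1000)}
#' where \eqn{\delta^{13}C_a} is the isotopic value of atmospheric CO2 and
#' \eqn{\delta^{13}C_{tree}} that of the plant tissue, both in permil VPDB.
#'
#' @param d13c_air Atmospheric delta-13C (permil).
#' @param d13c_tree Tissue delta-13C (permil, must exceed -1000).
#' @return Discrimination in permil.
#' @export
discrimination <- function(d13c_air, d13c_tree) {
  if (any(d13c_tree <= -1000))
    stop_br("discrimination: d13c_tree must exceed -1000 permil")
  (d13c_air - d13c_tree) / (1 + d13c_tree / 1000)
}

#' @rdname discrimination
#' @param delta Discrimination (permil); the inverse map recovers the
#'   tissue value that would produce it.
#' @export
d13c_from_discrimination <- function(delta, d13c_air) {
  (d13c_air - delta) / (1 + delta / 1000)
}

#' Extrapolate the atmospheric reference series
#'
#' Extends the annual atmospheric delta-13C and CO2 concentration series by
#' ordinary least squares lines fit over \code{fit_span} (separately for
#' each column), predicting \code{target_span}. Extrapolated years are
#' flagged.
#'
#' @param ref Data frame with \code{year}, \code{d13c_air} (permil) and
#'   \code{ca} (umol/mol).
#' @param fit_span Years of the fit (default 1993:2002); must be fully
#'   present.
#' @param target_span Years to append (default 2003:2012).
#' @return \code{ref} with appended rows and a logical column
#'   \code{extrapolated}.
#' @export
extrapolate_reference <- function(ref, fit_span = 1993:2002,
                                  target_span = 2003:2012) {
  if (!all(fit_span %in% ref$year))
    stop_br("extrapolate_reference: fit span years missing: ",
            paste(setdiff(fit_span, ref$year), collapse = ", "))
  if (!"extrapolated" %in% names(ref)) ref$extrapolated <- FALSE
  fit_rows <- ref[match(fit_span, ref$year), ]
  new_years <- setdiff(target_span, ref$year)
  if (length(new_years) == 0L) return(ref)
  preds <- lapply(c("d13c_air", "ca"), function(col) {
    fit <- lm(y ~ year, data = data.frame(year = fit_span, y = fit_rows[[col]]))
    predict(fit, newdata = data.frame(year = new_years))
  })
  add <- data.frame(year = new_years, d13c_air = preds[[1L]], ca = preds[[2L]],
                    extrapolated = TRUE)
  for (col in setdiff(names(ref), names(add))) add[[col]] <- NA
  out <- rbind(ref, add[names(ref)])
  out[order(out$year), ]
}

#' Ci/Ca from discrimination
#'
#' \deqn{C_i/C_a = (\Delta^{13}C - a) / (b - a)} with \eqn{a} = 4.4 permil
#' (fractionation during diffusion through the stomata) and \eqn{b} = 27
#' permil (fractionation during carboxylation). The input discrimination
#' should be computed from offset-adjusted tissue delta-13C (see
#' \code{\link{physio_series}}). Values of delta outside \eqn{[a, b]} give
#' ratios outside \eqn{[0, 1]} and are flagged, not rejected.
#'
#' @param delta Discrimination (permil).
#' @param a,b Fractionation constants (permil).
#' @return Dimensionless ratio with attribute \code{out_of_range}.
#' @export
ci_over_ca <- function(delta, a = 4.4, b = 27) {
  r <- (delta - a) / (b - a)
  structure(r, out_of_range = which(r < 0 | r > 1))
}

#' Intrinsic water-use efficiency
#'
#' \deqn{iWUE = A / G_s = (C_a - C_i) \cdot (1/1.6),} the ratio of
#' photosynthesis (A) to stomatal conductance (Gs), in umol/mol; 1.6 is the
#' ratio of the diffusivities of water vapour and CO2 in air. A and Gs are
#' never estimated separately, only their ratio.
#'
#' @param ca Atmospheric CO2 (umol/mol, > 0).
#' @param ci Intercellular CO2 (umol/mol).
#' @return iWUE in umol/mol; negative values (ci > ca) are flagged via the
#'   \code{negative} attribute.
#' @export
iwue <- function(ca, ci) {
  if (any(ca <= 0)) stop_br("iwue: ca must be positive")
  w <- (ca - ci) * (1 / 1.6)
  structure(w, negative = which(w < 0))
}

#' Ring-age adjustment of discrimination
#'
#' Young trees tend to show greater discrimination (soil-respired CO2,
#' shade, shorter hydraulic path), so period contrasts must be separated
#' from the ring-age profile. A random-forest regression of discrimination
#' on ring age and time period (500 trees) provides permutation importances
#' for both predictors and partial-dependence values per period with ring
#' age held constant (default 100 years, close to the mean age of typical
#' isotope trees).
#'
#' @param records Data frame with columns \code{delta} (permil),
#'   \code{ring_age} (years) and \code{period} (factor or character).
#' @param hold_age Ring age at which period effects are evaluated.
#' @param n_tree Random-forest size (default 500).
#' @param seed RNG seed.
#' @param min_records,min_periods,min_age_range Input requirements: at
#'   least 30 records spanning at least 3 periods and 50 years of ring age.
#' @return List: \code{adjusted} (data frame of period and adjusted delta),
#'   \code{importance} (named vector, permutation importance of
#'   \code{ring_age} and \code{period}), \code{age_profile} (data frame of
#'   age and fitted delta), \code{model}.
#' @export
age_adjustment <- function(records, hold_age = 100, n_tree = 500L,
                           seed = NULL, min_records = 30L, min_periods = 3L,
                           min_age_range = 50) {
  need <- c("delta", "ring_age", "period")
  if (!all(need %in% names(records)))
    stop_br("age_adjustment: records need columns ", paste(need, collapse = ", "))
  records <- records[complete.cases(records[need]), ]
  periods <- sort(unique(as.character(records$period)))
  if (length(periods) < min_periods)
    stop_br("age_adjustment: ", length(periods), " period(s); need >= ", min_periods)
  if (nrow(records) < min_records)
    stop_br("age_adjustment: ", nrow(records), " records; need >= ", min_records)
  if (diff(range(records$ring_age)) < min_age_range)
    stop_br("age_adjustment: ring-age range below ", min_age_range, " years")
  df <- data.frame(delta = records$delta, ring_age = records$ring_age,
                   period = factor(as.character(records$period), levels = periods))
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(delta ~ ring_age + period, data = df,
                                   ntree = as.integer(n_tree),
                                   importance = TRUE)
  imp <- randomForest::importance(rf, type = 1L, scale = FALSE)
  importance <- setNames(as.numeric(imp), rownames(imp))
  adjusted <- vapply(periods, function(p)
    mean(predict(rf, data.frame(ring_age = hold_age,
                                period = factor(p, levels = periods)))),
    numeric(1L))
  ages <- seq(floor(min(df$ring_age)), ceiling(max(df$ring_age)))
  prof <- rowMeans(vapply(periods, function(p)
    predict(rf, data.frame(ring_age = ages,
                           period = factor(rep(p, length(ages)), levels = periods))),
    numeric(length(ages))))
  list(adjusted = data.frame(period = periods, delta_adjusted = adjusted),
       importance = importance,
       age_profile = data.frame(ring_age = ages, delta_fitted = prof),
       model = rf)
}

period_years <- function(period) {
  parts <- as.integer(strsplit(as.character(period), "-")[[1L]])
  if (length(parts) != 2L || anyNA(parts))
    stop_br("period_years: period label must be 'start-end': ", period)
  seq(parts[1L], parts[2L])
}

#' Period-level gas-exchange physiology series
#'
#' For each species and time period: the mean measured discrimination (with
#' standard error), the ring-age-adjusted discrimination, and the derived
#' Ci/Ca, Ci and iWUE. Discrimination for the gas-exchange chain is
#' computed from offset-adjusted cellulose delta-13C (default offset -1.33
#' permil, correcting alpha-cellulose enrichment relative to leaf tissue);
#' the reported raw discrimination is unadjusted. Period-level atmospheric
#' values are arithmetic means of the annual reference over the period's
#' years (extrapolated automatically when the reference ends before a
#' period).
#'
#' @param records Data frame with \code{tree_id}, \code{species},
#'   \code{period} (labels like \code{"1895-1904"}), \code{d13c_cellulose}
#'   (permil VPDB) and \code{ring_age}; optionally \code{habitat_class}.
#' @param ref Atmospheric reference data frame (\code{year},
#'   \code{d13c_air}, \code{ca}).
#' @param offset Cellulose offset in permil (default -1.33), applied to
#'   delta-13C before Eq.-1-style discrimination for the Ci/Ca chain only.
#' @param hold_age,n_tree,seed Passed to \code{\link{age_adjustment}}.
#' @param by_habitat If \code{TRUE}, results are additionally stratified by
#'   \code{habitat_class}.
#' @return Data frame with one row per species x period (x habitat class),
#'   columns \code{delta_raw_mean}, \code{delta_raw_se},
#'   \code{delta_adjusted}, \code{ci_over_ca}, \code{ci}, \code{iwue},
#'   \code{d13c_air}, \code{ca}, \code{n_trees}.
#' @export
physio_series <- function(records, ref, offset = -1.33, hold_age = 100,
                          n_tree = 500L, seed = NULL, by_habitat = FALSE) {
  stopifnot(all(c("tree_id", "species", "period", "d13c_cellulose",
                  "ring_age") %in% names(records)))
  if (any(records$d13c_cellulose <= -40 | records$d13c_cellulose >= 0))
    warning("physio_series: d13c_cellulose outside (-40, 0) permil", call. = FALSE)
  periods <- sort(unique(as.character(records$period)))
  pyears <- lapply(setNames(nm = periods), period_years)
  need_years <- sort(unique(unlist(pyears)))
  if (!all(need_years %in% ref$year)) {
    ref <- tryCatch(extrapolate_reference(ref), error = function(e) ref)
    if (!all(need_years %in% ref$year))
      stop_br("physio_series: reference does not cover years ",
              paste(range(setdiff(need_years, ref$year)), collapse = "-"))
  }
  atm <- do.call(rbind, lapply(periods, function(p) {
    rows <- match(pyears[[p]], ref$year)
    data.frame(period = p, d13c_air = mean(ref$d13c_air[rows]),
               ca = mean(ref$ca[rows]))
  }))
  groups <- if (by_habitat) {
    stopifnot("habitat_class" %in% names(records))
    split(records, list(records$species, records$habitat_class), drop = TRUE)
  } else {
    split(records, records$species)
  }
  out <- lapply(names(groups), function(g) {
    rec <- groups[[g]]
    air <- atm$d13c_air[match(as.character(rec$period), atm$period)]
    delta_raw <- discrimination(air, rec$d13c_cellulose)
    delta_off <- discrimination(air, rec$d13c_cellulose + offset)
    adj <- age_adjustment(data.frame(delta = delta_off, ring_age = rec$ring_age,
                                     period = rec$period),
                          hold_age = hold_age, n_tree = n_tree, seed = seed)
    adj_raw <- age_adjustment(data.frame(delta = delta_raw, ring_age = rec$ring_age,
                                         period = rec$period),
                              hold_age = hold_age, n_tree = n_tree, seed = seed)
    per <- sort(unique(as.character(rec$period)))
    rows <- lapply(per, function(p) {
      sel <- as.character(rec$period) == p
      n <- sum(sel)
      a_row <- atm[atm$period == p, ]
      d_adj <- adj$adjusted$delta_adjusted[adj$adjusted$period == p]
      ratio <- as.numeric(ci_over_ca(d_adj))
      ci <- ratio * a_row$ca
      data.frame(group = g,
                 species = rec$species[which(sel)[1L]],
                 habitat_class = if (by_habitat) rec$habitat_class[which(sel)[1L]] else NA,
                 period = p, n_trees = n,
                 delta_raw_mean = mean(delta_raw[sel]),
                 delta_raw_se = if (n > 1L) sd(delta_raw[sel]) / sqrt(n) else NA_real_,
                 delta_raw_adjusted = adj_raw$adjusted$delta_adjusted[adj_raw$adjusted$period == p],
                 delta_adjusted = d_adj,
                 ci_over_ca = ratio, ci = ci,
                 iwue = as.numeric(iwue(a_row$ca, ci)),
                 d13c_air = a_row$d13c_air, ca = a_row$ca)
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  se_na <- res$n_trees < 2L
  if (any(se_na))
    br_log("physio_series: SE undefined (single record) for ",
           sum(se_na), " period group(s)")
  rownames(res) <- NULL
  res
}

#' Read per-tree isotope records
#'
#' @param path CSV with columns \code{tree_id}, \code{species},
#'   \code{period}, \code{d13c_cellulose} (or \code{d13c}),
#'   \code{ring_age}, optional \code{habitat_class}.
#' @return Data frame.
#' @export
read_isotopes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("d13c" %in% names(df) && !"d13c_cellulose" %in% names(df))
    names(df)[names(df) == "d13c"] <- "d13c_cellulose"
  need <- c("tree_id", "species", "period", "d13c_cellulose", "ring_age")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_br("read_isotopes: missing columns: ",
                            paste(miss, collapse = ", "))
  df
}

#' Read the atmospheric reference series
#'
#' @param path CSV with columns \code{year}, \code{d13c_air}, \code{ca}
#'   (and optionally \code{provenance}).
#' @return Data frame.
#' @export
read_reference <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "d13c_air", "ca")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_br("read_reference: missing columns: ",
                            paste(miss, collapse = ", "))
  df[order(df$year), ]
}
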