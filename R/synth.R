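## Synthetic ring-width, climate, isotope and habitat data with known
## ground truth. The generator emulates the statistical structure the
## analysis assumes: negative-exponential age trends with lognormal
## between-tree growth rates, a shared year signal driven by a decreasing
## sigmoid of growing-season temperature and a saturating ramp of August
## precipitation, habitat-dependent level and sensitivity differences,
## multiplicative lognormal ring noise, and isotope series with a strong
## juvenile decline in discrimination over the first 50-70 rings.

#' Synthetic-study configuration
#'
#' @param seed Mandatory RNG seed.
#' @param profile \code{"default"} (150 trees, 150 years, noise sd 0.2 --
#'   the standard recovery cohort), \code{"field"} (213 black + 339 white
#'   spruce, the field study's scale) or \code{"ci"} (60 trees/species, a
#'   fast profile).
#' @param ... Named overrides of any configuration element (see Details).
#' @details Elements: \code{years}; \code{n_trees} (named per species);
#'   \code{germination_span}; \code{age_trend} (\code{alpha_meanlog},
#'   \code{alpha_sdlog}, \code{beta}, \code{kappa}: expected width
#'   \eqn{w(a)=\alpha e^{-\beta a}+\kappa} mm, per-tree alpha lognormal);
#'   \code{noise_sigma} (lognormal ring noise); \code{climate}
#'   (climatology, AR(1) coefficient and anomaly sd for temperature,
#'   post-onset linear trend, lognormal precipitation); \code{forcing}
#'   (temperature sigmoid midpoint/steepness/floor; precipitation ramp
#'   thresholds 40/80 mm and floor); \code{habitat} (class proportions,
#'   level multipliers, temperature-sensitivity exponents, optional
#'   moss-threshold growth effect); \code{missing_pith_frac};
#'   \code{fire_frac}; \code{isotope} (baseline, juvenile decline
#'   depth/timescale, slow rise per century, period effects, measurement
#'   sd, the five standard periods).
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(seed, profile = c("default", "field", "ci"), ...) {
  if (missing(seed)) stop_br("synth_config: seed is mandatory")
  profile <- match.arg(profile)
  n_trees <- switch(profile,
                    default = c(black_spruce = 75L, white_spruce = 75L),
                    field = c(black_spruce = 213L, white_spruce = 339L),
                    ci = c(black_spruce = 60L, white_spruce = 60L))
  cfg <- list(
    seed = as.integer(seed),
    profile = profile,
    years = 1864:2013,
    n_trees = n_trees,
    germination_span = 1864:1894,
    trees_per_plot = 5L,
    age_trend = list(alpha_meanlog = log(1.8), alpha_sdlog = 0.25,
                     beta = 0.025, kappa = 0.15),
    noise_sigma = 0.2,
    climate = list(
      t_clim = c(-23, -19, -11, -1, 9, 15, 17, 14, 7, -4, -16, -21),
      t_ar1 = 0.5, t_sd = 1.5, trend_onset = 1965, trend_slope = 0.03,
      p_mean = c(15, 11, 9, 8, 17, 35, 50, 45, 30, 20, 16, 14),
      p_sdlog = 0.5),
    forcing = list(t_mid = 14.0, t_steep = 1.5, t_floor = 0.6,
                   p_lo = 40, p_hi = 80, p_floor = 0.7,
                   t_prev_weight = 0.8, p_prev_weight = 0.3),
    habitat = list(p_good = 0.35, p_poor = 0.35,
                   level = c(good = 1, poor = 1, unclassified = 1),
                   sens_t = c(good = 1, poor = 1, unclassified = 1),
                   moss_effect = 0),
    missing_pith_frac = 0.3,
    fire_frac = 0,
    isotope = list(
      baseline = c(black_spruce = 17.0, white_spruce = 18.0),
      juv_depth = c(black_spruce = 0.5, white_spruce = 1.5),
      juv_tau = 18, slow_rise = 0.25, sigma_meas = 0.3,
      periods = c("1895-1904", "1930-1949", "1950-1959",
                  "1993-2002", "2003-2012"),
      period_effects = c("1895-1904" = 0, "1930-1949" = 0, "1950-1959" = 0,
                         "1993-2002" = 0, "2003-2012" = 0)),
    reference = list(start = 1850, end = 2002)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic monthly climate record
#'
#' Monthly temperature = seasonal climatology + AR(1) anomalies + a linear
#' warming trend after the onset year; monthly precipitation is lognormal.
#'
#' @param config A \code{synth_config}.
#' @return List: \code{climate} (a \code{climate_table}) and \code{truth}
#'   (anomaly matrix and the trend applied).
#' @export
generate_climate <- function(config) {
  years <- config$years
  if (length(years) < 60L) stop_br("generate_climate: span must be >= 60 years")
  set.seed(derive_seed(config$seed, 1L))
  cl <- config$climate
  n <- length(years)
  anom <- matrix(0, n, 12L)
  for (m in 1:12) {
    e <- rnorm(n, sd = cl$t_sd * sqrt(1 - cl$t_ar1^2))
    a <- numeric(n); a[1L] <- rnorm(1L, sd = cl$t_sd)
    for (i in 2:n) a[i] <- cl$t_ar1 * a[i - 1L] + e[i]
    anom[, m] <- a
  }
  trend <- cl$trend_slope * pmax(0, years - cl$trend_onset)
  Tm <- sweep(anom, 2L, cl$t_clim, `+`) + trend
  sdl <- cl$p_sdlog
  Pm <- vapply(1:12, function(m)
    rlnorm(n, meanlog = log(cl$p_mean[m]) - sdl^2 / 2, sdlog = sdl),
    numeric(n))
  df <- data.frame(year = years)
  for (m in 1:12) df[[sprintf("t%02d", m)]] <- Tm[, m]
  for (m in 1:12) df[[sprintf("p%02d", m)]] <- Pm[, m]
  list(climate = climate_table(df),
       truth = list(anomalies = anom, trend = trend))
}

## The two forcing response functions: a decreasing sigmoid of May-August
## mean temperature and a saturating ramp of August precipitation.
forcing_temperature <- function(t_mjja, f) {
  f$t_floor + (1 - f$t_floor) / (1 + exp(f$t_steep * (t_mjja - f$t_mid)))
}

forcing_precipitation <- function(p_aug, f) {
  ramp <- pmin(1, pmax(0, (p_aug - f$p_lo) / (f$p_hi - f$p_lo)))
  f$p_floor + (1 - f$p_floor) * ramp
}

draw_plot_covariates <- function(species, hab) {
  u <- runif(1L)
  if (species == "black_spruce") {
    if (u < hab$p_good) {
      slope <- runif(1L, 16, 30); moss <- runif(1L, 62, 95)
    } else if (u < hab$p_good + hab$p_poor) {
      slope <- runif(1L, 0, 14); moss <- runif(1L, 5, 58)
    } else {
      slope <- runif(1L, 16, 30); moss <- runif(1L, 5, 58)
    }
    duff <- runif(1L, 2, 20)
  } else {
    if (u < hab$p_good) {
      moss <- runif(1L, 5, 48); duff <- runif(1L, 1, 9)
    } else if (u < hab$p_good + hab$p_poor) {
      moss <- runif(1L, 52, 95); duff <- runif(1L, 11, 25)
    } else {
      moss <- runif(1L, 5, 48); duff <- runif(1L, 11, 25)
    }
    slope <- runif(1L, 0, 25)
  }
  list(moss_cover = moss, duff_depth = duff, slope = slope,
       basal_area = rlnorm(1L, log(18), 0.4),
       elevation = runif(1L, 130, 900),
       litter_depth = runif(1L, 0.5, 6),
       moss_effect_driver = moss,
       aspect = sample(c("north", "south", "east", "west", "flat"), 1L),
       region = sample(c("NW", "NC", "SC", "SE"), 1L),
       stand_density = rlnorm(1L, log(1200), 0.5),
       topographic_position = sample(c("upper", "mid", "lower",
                                       "alluvial_flat", "dry_flat",
                                       "wet_flat"), 1L),
       stand_type = sample(c("black_spruce", "white_spruce", "paper_birch",
                             "balsam_poplar", "trembling_aspen"), 1L,
                           prob = c(0.4, 0.4, 0.1, 0.05, 0.05)))
}

#' Generate a synthetic tree cohort
#'
#' Ring width of tree \eqn{t} in year \eqn{y} is
#' \deqn{w_t(a)\, C_h(y)\, m_t\, \varepsilon_{ty}} with
#' \eqn{w_t(a) = \alpha_t e^{-\beta a} + \kappa} (cambial age \eqn{a}),
#' \eqn{C_h(y)} the habitat-class common signal (temperature sigmoid raised
#' to the class sensitivity exponent times the precipitation ramp,
#' normalized to mean 1), \eqn{m_t} the class level multiplier (optionally
#' modulated by a moss-cover threshold), and lognormal noise. A configured
#' fraction of trees misses the pith: their first rings are withheld and
#' replaced by arc (chord/height) metadata consistent with the true
#' missing radius.
#'
#' @param config A \code{synth_config}.
#' @param climate Optional result of \code{\link{generate_climate}} (it is
#'   generated from the config when absent).
#' @return A \code{synth_cohort} list: \code{series} (a \code{ring_set},
#'   with true missing-ring counts set), \code{metadata} (per-series data
#'   frame with arc measurements and fire years), \code{plots} (per-plot
#'   covariates with habitat class), \code{climate}, and \code{truth}
#'   (common signal per habitat class, per-tree parameters, the config).
#' @export
generate_cohort <- function(config, climate = NULL) {
  if (is.null(climate)) climate <- generate_climate(config)
  ct <- climate$climate
  years <- config$years
  if (!all(years %in% ct$year)) stop_br("generate_cohort: climate does not cover the cohort span")
  set.seed(derive_seed(config$seed, 2L))
  f <- config$forcing
  t_mjja <- ct$t_mjja[match(years, ct$year)]
  p_aug <- ct$p08[match(years, ct$year)]
  fT <- forcing_temperature(t_mjja, f)
  fP <- forcing_precipitation(p_aug, f)
  ## Previous-year carryover (stored reserves): lagged responses enter with
  ## reduced weight, mirroring the strong previous-summer correlations seen
  ## in boreal conifer chronologies. First year uses a neutral lag term.
  lag1 <- function(v) c(v[1L], v[-length(v)])
  fTl <- lag1(fT)^(f$t_prev_weight %||% 0)
  fPl <- lag1(fP)^(f$p_prev_weight %||% 0)
  hab <- config$habitat
  classes <- c("good", "poor", "unclassified")
  C <- vapply(classes, function(h) {
    x <- (fT * fTl)^hab$sens_t[[h]] * fP * fPl
    x / mean(x)
  }, numeric(length(years)))
  colnames(C) <- classes
  series <- list(); meta <- list(); plots <- list(); params <- list()
  at <- config$age_trend
  end_year <- max(years)
  for (sp in names(config$n_trees)) {
    n <- config$n_trees[[sp]]
    n_plots <- ceiling(n / config$trees_per_plot)
    plot_ids <- sprintf("%s_P%02d", toupper(substr(sp, 1L, 2L)), seq_len(n_plots))
    plot_cov <- lapply(seq_len(n_plots), function(i) draw_plot_covariates(sp, hab))
    plot_class <- vapply(seq_len(n_plots), function(i)
      classify_habitat(plot_cov[[i]], species = sp), character(1L))
    fire_years <- rep(NA_integer_, n_plots)
    if (config$fire_frac > 0) {
      burned <- runif(n_plots) < config$fire_frac
      fire_years[burned] <- sample(1965:2005, sum(burned), replace = TRUE)
    }
    for (i in seq_len(n)) {
      id <- sprintf("%s%03d", toupper(substr(sp, 1L, 2L)), i)
      plot_i <- ((i - 1L) %/% config$trees_per_plot) + 1L
      cls <- plot_class[plot_i]
      germ <- sample(config$germination_span, 1L)
      yrs <- germ:end_year
      ages <- seq_along(yrs)
      alpha <- rlnorm(1L, at$alpha_meanlog, at$alpha_sdlog)
      w_age <- alpha * exp(-at$beta * ages) + at$kappa
      lev <- hab$level[[cls]]
      if (hab$moss_effect != 0) {
        moss <- plot_cov[[plot_i]]$moss_cover
        lev <- lev * (1 + hab$moss_effect / (1 + exp(-0.3 * (moss - 60))))
      }
      eps <- rlnorm(length(yrs), -config$noise_sigma^2 / 2, config$noise_sigma)
      widths <- w_age * C[match(yrs, years), cls] * lev * eps
      miss_k <- 0L; chord <- NA_real_; height <- NA_real_; radius <- NA_real_
      pith <- TRUE
      if (runif(1L) < config$missing_pith_frac && length(widths) > 30L) {
        miss_k <- sample(3:15, 1L)
        radius <- sum(widths[seq_len(miss_k)])
        height <- 0.6 * radius
        chord <- sqrt((radius - height / 2) * 8 * height)
        widths <- widths[-seq_len(miss_k)]
        yrs <- yrs[-seq_len(miss_k)]
        pith <- FALSE
      }
      s <- ring_series(series_id = id, tree_id = id, plot_id = plot_ids[plot_i],
                       species = sp, plot_type = if (runif(1L) < 0.9) "FIA" else "AIRIS",
                       first_year = yrs[1L], widths = widths,
                       pith_present = pith,
                       missing_radius_mm = if (pith) 0 else radius,
                       missing_rings = if (pith) 0L else miss_k,
                       fire_year = fire_years[plot_i])
      series[[id]] <- s
      meta[[id]] <- data.frame(
        series_id = id, tree_id = id, plot_id = plot_ids[plot_i],
        species = sp, plot_type = s$plot_type, pith_present = pith,
        chord_mm = chord, height_mm = height,
        fire_year = fire_years[plot_i])
      params[[id]] <- data.frame(
        series_id = id, species = sp, plot_id = plot_ids[plot_i],
        habitat_class = cls, germination_year = germ, alpha = alpha,
        beta = at$beta, kappa = at$kappa,
        missing_rings_true = miss_k, missing_radius_true = radius)
    }
    sp_params <- do.call(rbind, params[vapply(params, function(d)
      d$species == sp, logical(1L))])
    for (i in seq_len(n_plots)) {
      cov <- plot_cov[[i]]
      cov$moss_effect_driver <- NULL
      germ_mean <- mean(sp_params$germination_year[sp_params$plot_id == plot_ids[i]])
      plots[[plot_ids[i]]] <- data.frame(
        plot_id = plot_ids[i], species = sp,
        as.data.frame(cov, stringsAsFactors = FALSE),
        habitat_class = plot_class[i],
        stand_age = round(end_year - germ_mean), check.names = FALSE)
    }
  }
  signal <- data.frame(year = years, C)
  structure(list(series = ring_set(series),
                 metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
                 plots = do.call(rbind, c(plots, list(make.row.names = FALSE))),
                 climate = ct,
                 truth = list(signal = signal,
                              tree_params = do.call(rbind, c(params, list(make.row.names = FALSE))),
                              config = config)),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d trees (%s), years %d-%d\n",
              length(x$series),
              paste(names(table(x$truth$tree_params$species)),
                    table(x$truth$tree_params$species), collapse = " + "),
              min(x$truth$signal$year), max(x$truth$signal$year)))
  invisible(x)
}

#' Generate a synthetic atmospheric reference series
#'
#' Smoothly declining atmospheric delta-13C and accelerating CO2, shaped
#' like the industrial-era record but entirely synthetic.
#'
#' @param config A \code{synth_config}.
#' @return Data frame: \code{year}, \code{d13c_air}, \code{ca},
#'   \code{provenance} (always \code{"synthetic"}).
#' @export
generate_reference <- function(config) {
  years <- config$reference$start:config$reference$end
  t <- years - config$reference$start
  data.frame(year = years,
             d13c_air = -6.4 - 0.00012 * t^1.8,
             ca = 285 + 0.0035 * t^2,
             provenance = "synthetic")
}

#' Generate synthetic per-tree isotope records
#'
#' Discrimination for tree \eqn{t} in period \eqn{p} is
#' \deqn{\Delta = baseline_{sp} + d\,e^{-age/\tau} + s\,(age/100) +
#'   effect_p + N(0, \sigma):}
#' elevated in young rings and declining strongly over the first 50-70
#' rings, then rising slowly, plus any configured period effects; cellulose delta-13C is then
#' obtained by inverting the discrimination equation against the
#' synthetic atmospheric reference (period-mean values).
#'
#' @param config A \code{synth_config}.
#' @param cohort A \code{synth_cohort}.
#' @param n_per_species Trees per species to sample for isotopes (default
#'   85); trees must cover a period to contribute a record.
#' @return List: \code{records} (per tree x period data frame with
#'   \code{d13c_cellulose}, \code{ring_age}, \code{habitat_class}),
#'   \code{reference}, \code{truth} (target discrimination per record and
#'   the period effects).
#' @export
generate_isotopes <- function(config, cohort, n_per_species = 85L) {
  set.seed(derive_seed(config$seed, 3L))
  iso <- config$isotope
  ref <- generate_reference(config)
  ref_use <- extrapolate_reference(ref)
  tp <- cohort$truth$tree_params
  recs <- list(); truth <- list()
  for (sp in unique(tp$species)) {
    cand <- tp$series_id[tp$species == sp]
    pick <- cand[seq_len(min(n_per_species, length(cand)))]
    for (id in pick) {
      s <- cohort$series[[id]]
      yrs <- series_years(s)
      ages_all <- cambial_ages(s)
      cls <- tp$habitat_class[tp$series_id == id]
      for (p in iso$periods) {
        py <- period_years(p)
        sel <- yrs %in% py
        if (sum(sel) < length(py) / 2) next  # tree must cover most of the period
        age <- mean(ages_all[sel])
        delta <- iso$baseline[[sp]] + iso$juv_depth[[sp]] * exp(-age / iso$juv_tau) +
          iso$slow_rise * (age / 100) + iso$period_effects[[p]] +
          rnorm(1L, sd = iso$sigma_meas)
        d13c_air <- mean(ref_use$d13c_air[match(py, ref_use$year)])
        recs[[length(recs) + 1L]] <- data.frame(
          tree_id = id, species = sp, period = p,
          d13c_cellulose = d13c_from_discrimination(delta, d13c_air),
          ring_age = age, habitat_class = cls)
        truth[[length(truth) + 1L]] <- data.frame(
          tree_id = id, species = sp, period = p, delta_true = delta)
      }
    }
  }
  list(records = do.call(rbind, c(recs, list(make.row.names = FALSE))),
       reference = ref,
       truth = list(records = do.call(rbind, c(truth, list(make.row.names = FALSE))),
                    period_effects = iso$period_effects))
}

#' Per-tree habitat records for the habitat BRT analysis
#'
#' Joins each tree's recent mean ring-width index to its plot's locational
#' and structural covariates.
#'
#' @param cohort A \code{synth_cohort}.
#' @param ind Years x trees ring-width index matrix (from a detrending
#'   fit).
#' @param span Averaging span (default 2003:2012).
#' @param delta13c Optional named per-plot mean discrimination to include
#'   as a covariate.
#' @return Data frame of habitat records (one row per tree).
#' @export
habitat_records <- function(cohort, ind, span = 2003:2012, delta13c = NULL) {
  rwi <- recent_mean_rwi(ind, span = span)
  tp <- cohort$truth$tree_params
  rwi$plot_id <- tp$plot_id[match(rwi$series_id, tp$series_id)]
  rwi$species <- tp$species[match(rwi$series_id, tp$series_id)]
  plots <- cohort$plots
  out <- cbind(rwi, plots[match(rwi$plot_id, plots$plot_id),
                          setdiff(names(plots), c("plot_id", "species")),
                          drop = FALSE])
  if (!is.null(delta13c)) out$delta13c <- as.numeric(delta13c[out$plot_id])
  rownames(out) <- NULL
  out
}

#' Write a synthetic dataset to disk
#'
#' Emits the file set the pipeline consumes: the RWL ring-width file, the
#' tree metadata CSV, the monthly climate CSV, the atmospheric reference
#' CSV, the isotope records CSV and the plot habitat CSV.
#'
#' @param cohort A \code{synth_cohort}.
#' @param dir Output directory (created if needed).
#' @param isotopes Optional result of \code{\link{generate_isotopes}}.
#' @return Named vector of file paths, invisibly.
#' @export
write_synth_dataset <- function(cohort, dir, isotopes = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(rwl = file.path(dir, "rings.rwl"),
             metadata = file.path(dir, "tree_metadata.csv"),
             climate = file.path(dir, "climate.csv"),
             plots = file.path(dir, "plots.csv"),
             signal = file.path(dir, "truth_signal.csv"))
  write_rwl(cohort$series, paths[["rwl"]])
  write.csv(cohort$metadata, paths[["metadata"]], row.names = FALSE)
  cl <- as.data.frame(cohort$climate)
  write.csv(cl[, c("year", sprintf("t%02d", 1:12), sprintf("p%02d", 1:12))],
            paths[["climate"]], row.names = FALSE)
  write.csv(cohort$plots, paths[["plots"]], row.names = FALSE)
  write.csv(cohort$truth$signal, paths[["signal"]], row.names = FALSE)
  if (!is.null(isotopes)) {
    paths[["isotopes"]] <- file.path(dir, "isotopes.csv")
    paths[["reference"]] <- file.path(dir, "reference_atmosphere.csv")
    write.csv(isotopes$records, paths[["isotopes"]], row.names = FALSE)
    write.csv(isotopes$reference, paths[["reference"]], row.names = FALSE)
  }
  invisible(paths)
}
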