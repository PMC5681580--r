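## Monthly station climate and the climate-growth variable set.

#' Monthly climate table
#'
#' Holds monthly mean air temperature (degrees C) and precipitation totals
#' (mm) by calendar year, plus derived seasonal aggregates: May-August mean
#' temperature, May-August precipitation total, and the October-April
#' precipitation total, which spans the year boundary and is assigned to
#' the later (growth) year.
#'
#' @param x A data frame with columns \code{year}, \code{t01}..\code{t12}
#'   and \code{p01}..\code{p12}, or a path to such a CSV.
#' @return A \code{climate_table} data frame with the seasonal columns
#'   \code{t_mjja}, \code{p_mjja} and \code{p_octapr} appended.
#' @export
climate_table <- function(x) {
  df <- if (is.character(x)) read.csv(x) else as.data.frame(x)
  tcols <- sprintf("t%02d", 1:12)
  pcols <- sprintf("p%02d", 1:12)
  miss <- setdiff(c("year", tcols, pcols), names(df))
  if (length(miss)) stop_br("climate_table: missing columns: ",
                            paste(miss, collapse = ", "))
  df <- df[order(df$year), ]
  if (!all(diff(df$year) == 1L)) stop_br("climate_table: years must be contiguous")
  if (any(df[pcols] < 0, na.rm = TRUE)) stop_br("climate_table: negative precipitation")
  df$t_mjja <- rowMeans(df[, sprintf("t%02d", 5:8)])
  df$p_mjja <- rowSums(df[, sprintf("p%02d", 5:8)])
  prev <- match(df$year - 1L, df$year)
  oct_dec_prev <- rowSums(df[prev, sprintf("p%02d", 10:12), drop = FALSE])
  jan_apr <- rowSums(df[, sprintf("p%02d", 1:4)])
  df$p_octapr <- oct_dec_prev + jan_apr  # NA in the first year
  structure(df, class = c("climate_table", "data.frame"))
}

#' Climate variable set for climate-growth analysis
#'
#' Builds the analysis variables: monthly mean temperature May-August and
#' monthly precipitation May-August for the growth year and (lagged exactly
#' one year) the previous year, plus the seasonal May-August and
#' October-April precipitation totals for both years. The sixteen monthly
#' variables form the standard correlation grid; the seasonal totals are
#' supplementary.
#'
#' @param climate A \code{climate_table}.
#' @return A data frame (\code{year} + variables) with attribute
#'   \code{var_info}: a data frame of \code{variable}, \code{is_precip},
#'   \code{monthly}.
#' @export
climate_variables <- function(climate) {
  stopifnot(inherits(climate, "climate_table"))
  months <- c(may = 5L, jun = 6L, jul = 7L, aug = 8L)
  out <- data.frame(year = climate$year)
  prev <- match(climate$year - 1L, climate$year)
  for (m in names(months)) {
    out[[paste0("t_", m)]] <- climate[[sprintf("t%02d", months[[m]])]]
    out[[paste0("t_", m, "_prev")]] <- climate[[sprintf("t%02d", months[[m]])]][prev]
    out[[paste0("p_", m)]] <- climate[[sprintf("p%02d", months[[m]])]]
    out[[paste0("p_", m, "_prev")]] <- climate[[sprintf("p%02d", months[[m]])]][prev]
  }
  out$p_mjja <- climate$p_mjja
  out$p_mjja_prev <- climate$p_mjja[prev]
  out$p_octapr <- climate$p_octapr
  out$p_octapr_prev <- climate$p_octapr[prev]
  vars <- setdiff(names(out), "year")
  info <- data.frame(variable = vars,
                     is_precip = grepl("^p_", vars),
                     monthly = vars %in% as.vector(outer(
                       c("t_", "p_"), names(months),
                       function(a, b) paste0(a, b))) |
                       vars %in% as.vector(outer(
                         c("t_", "p_"), names(months),
                         function(a, b) paste0(a, b, "_prev"))))
  attr(out, "var_info") <- info
  out
}

## Natural-log transform for precipitation; the +0.1 mm offset keeps
## zero-precipitation months representable.
log_precip <- function(x, offset = 0.1) log(x + offset)

## Apply the precipitation transform to the variable columns named
## in var_info; temperatures pass through unchanged.
transform_climate_vars <- function(climvars, offset = 0.1) {
  info <- attr(climvars, "var_info")
  for (v in info$variable[info$is_precip]) climvars[[v]] <- log_precip(climvars[[v]], offset)
  climvars
}
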