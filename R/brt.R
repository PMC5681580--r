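## Boosted regression trees for nonlinear climate-growth and habitat
## analysis. The engine is gradient boosting with squared-error loss,
## shallow trees (interaction depth = "tree complexity"), a small learning
## rate and bagging, with the number of trees chosen by k-fold
## cross-validation up to a cap.

## One-hot encode a mixed data frame; returns the numeric matrix and a map
## from encoded feature names to source variable names. NAs pass through
## (handled natively by the tree learner).
encode_predictors <- function(df) {
  cols <- list(); map <- character(0)
  for (v in names(df)) {
    x <- df[[v]]
    if (is.character(x)) x <- factor(x)
    if (is.factor(x)) {
      for (lev in levels(x)) {
        nm <- paste0(v, "=", lev)
        cols[[nm]] <- as.numeric(x == lev)
        map[nm] <- v
      }
    } else {
      cols[[v]] <- as.numeric(x)
      map[v] <- v
    }
  }
  list(mat = do.call(cbind, cols), map = map)
}

#' Fit a boosted regression tree model
#'
#' @param data Data frame of predictors (numeric, character or factor).
#' @param y Numeric response.
#' @param tree_complexity Maximum tree depth, controlling the interaction
#'   order (default 2).
#' @param learning_rate Shrinkage per tree (default 0.001).
#' @param bag_fraction Row subsample fraction per tree (default 0.5).
#' @param max_trees Cap on the number of trees (default 30000).
#' @param cv_folds Folds for tree-count selection (default 10).
#' @param min_rows Minimum number of complete-response rows (default 50).
#' @param seed RNG seed (folds and bagging).
#' @param pd_grid Grid size for partial-dependence curves.
#' @param interaction_top Number of top-influence variables screened for
#'   pairwise interactions (default 6).
#' @return A \code{brt_model}: list with \code{model}, \code{best_trees},
#'   \code{r_squared}, \code{influence} (summing to 100),
#'   \code{partial_dependence} (list of data frames),
#'   \code{interactions} (pairwise H-statistics), \code{fitted}.
#' @export
fit_brt <- function(data, y, tree_complexity = 2L, learning_rate = 0.001,
                    bag_fraction = 0.5, max_trees = 30000L, cv_folds = 10L,
                    min_rows = 50L, seed = NULL, pd_grid = 50L,
                    interaction_top = 6L) {
  ok <- is.finite(y)
  data <- data[ok, , drop = FALSE]; y <- y[ok]
  if (nrow(data) < min_rows)
    stop_br("fit_brt: ", nrow(data), " rows; need >= ", min_rows)
  const <- vapply(data, function(x) length(unique(x[!is.na(x)])) < 2L, logical(1L))
  if (any(const)) {
    warning("fit_brt: dropping constant predictor(s): ",
            paste(names(data)[const], collapse = ", "), call. = FALSE)
    data <- data[, !const, drop = FALSE]
  }
  enc <- encode_predictors(data)
  X <- enc$mat
  if (!is.null(seed)) set.seed(seed)
  params <- list(max_depth = as.integer(tree_complexity), eta = learning_rate,
                 subsample = bag_fraction, objective = "reg:squarederror",
                 nthread = 1L)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  cv <- xgboost::xgb.cv(params = params, data = dtrain,
                        nrounds = as.integer(max_trees),
                        nfold = as.integer(cv_folds), verbose = 0,
                        early_stopping_rounds = max(100L, as.integer(max_trees / 10L)))
  best <- which.min(cv$evaluation_log$test_rmse_mean)
  model <- xgboost::xgb.train(params = params, data = dtrain, nrounds = best,
                              verbose = 0)
  fitted <- predict(model, X)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  imp <- xgboost::xgb.importance(model = model)
  gain <- setNames(rep(0, ncol(X)), colnames(X))
  gain[imp$Feature] <- imp$Gain
  by_var <- tapply(gain, enc$map[names(gain)], sum)
  infl <- 100 * by_var / sum(by_var)
  influence <- data.frame(variable = names(infl), influence = as.numeric(infl))
  influence <- influence[order(-influence$influence), ]
  rownames(influence) <- NULL
  obj <- structure(list(model = model, best_trees = best, r_squared = r2,
                        influence = influence, fitted = fitted, y = y,
                        X = X, map = enc$map, data = data,
                        params = params),
                   class = "brt_model")
  obj$partial_dependence <- lapply(setNames(nm = names(data)), function(v)
    brt_partial_dependence(obj, v, grid = pd_grid))
  top <- head(influence$variable, interaction_top)
  obj$interactions <- brt_interactions(obj, top)
  obj
}

#' @export
print.brt_model <- function(x, ...) {
  cat(sprintf("<brt_model> %d trees (CV-selected), R2 = %.3f\n",
              x$best_trees, x$r_squared))
  print(head(x$influence, 8L))
  invisible(x)
}

## Reference row: every encoded column at its training mean (for one-hot
## columns the mean is the level frequency).
reference_row <- function(obj) colMeans(obj$X, na.rm = TRUE)

pd_points <- function(obj, variable, grid) {
  x <- obj$data[[variable]]
  if (is.character(x)) x <- factor(x)
  if (is.factor(x)) levels(x) else {
    qs <- quantile(x, probs = seq(0.02, 0.98, length.out = grid),
                   na.rm = TRUE, names = FALSE)
    unique(qs)
  }
}

## Predictions over a grid of one (or two) variables with all other encoded
## columns held at their training means.
pd_predict <- function(obj, vals) {
  ref <- reference_row(obj)
  n <- max(vapply(vals, length, integer(1L)))
  New <- matrix(rep(ref, each = n), n, dimnames = list(NULL, names(ref)))
  for (v in names(vals)) {
    x <- vals[[v]]
    if (is.character(x)) {
      for (nm in names(obj$map)[obj$map == v])
        New[, nm] <- as.numeric(paste0(v, "=", x) == nm)
    } else {
      New[, v] <- x
    }
  }
  predict(obj$model, New)
}

#' Partial dependence of a fitted BRT model
#'
#' Modeled marginal response to one variable with all other predictors held
#' at their training means (one-hot levels at their frequencies).
#'
#' @param obj A \code{brt_model}.
#' @param variable Variable name.
#' @param grid Number of grid points for numeric variables.
#' @return Data frame with \code{value} and \code{yhat}.
#' @export
brt_partial_dependence <- function(obj, variable, grid = 50L) {
  pts <- pd_points(obj, variable, grid)
  yhat <- pd_predict(obj, setNames(list(pts), variable))
  data.frame(value = pts, yhat = yhat)
}

## Friedman-style H-statistic on a joint grid (others at means): the share
## of joint partial-dependence variance not explained additively.
brt_interactions <- function(obj, variables, grid = 15L) {
  if (length(variables) < 2L)
    return(data.frame(var1 = character(0), var2 = character(0), h = numeric(0)))
  pairs <- utils::combn(variables, 2L, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    p1 <- pd_points(obj, pr[1L], grid)
    p2 <- pd_points(obj, pr[2L], grid)
    g <- expand.grid(a = p1, b = p2, stringsAsFactors = FALSE)
    f12 <- pd_predict(obj, setNames(list(g$a, g$b), pr))
    f1 <- pd_predict(obj, setNames(list(p1), pr[1L]))
    f2 <- pd_predict(obj, setNames(list(p2), pr[2L]))
    f12 <- f12 - mean(f12)
    add <- (f1 - mean(f1))[match(g$a, p1)] + (f2 - mean(f2))[match(g$b, p2)]
    denom <- sum(f12^2)
    h <- if (denom <= 0) 0 else sqrt(max(0, sum((f12 - add)^2)) / denom)
    data.frame(var1 = pr[1L], var2 = pr[2L], h = h)
  })
  out <- do.call(rbind, res)
  out[order(-out$h), ]
}

#' Boosted regression tree analysis of climate-growth relationships
#'
#' Fits the BRT model of ring-width indices on the climate variable set
#' (precipitation log-transformed as in the correlation analyses), with
#' tree complexity 2, learning rate 0.001, bag fraction 0.5 and the tree
#' count selected by 10-fold cross-validation up to a 30000-tree cap.
#'
#' @inheritParams static_correlations
#' @param ... Passed to \code{\link{fit_brt}} (e.g. \code{max_trees},
#'   \code{seed}).
#' @return A \code{brt_model}.
#' @export
brt_climate_model <- function(chron, climvars, span = NULL, ...) {
  yrs <- intersect(chron$year, climvars$year)
  if (!is.null(span)) yrs <- intersect(yrs, span)
  yrs <- sort(yrs)
  cv <- transform_climate_vars(climvars)
  vars <- attr(climvars, "var_info")$variable
  df <- cv[match(yrs, cv$year), vars, drop = FALSE]
  y <- chron$index[match(yrs, chron$year)]
  keep <- complete.cases(df) & is.finite(y)
  fit_brt(df[keep, , drop = FALSE], y[keep], ...)
}
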