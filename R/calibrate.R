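# AOD <-> ground PM2.5 collocation, two-factor meteorological summary, and
# the empirical PM2.5 ~ AOD calibration regression.

#' Collocate AOD retrievals with ground PM2.5 records
#'
#' Pairs each satellite AOD retrieval with at most one ground monitor record
#' falling within both the temporal window (default 0.75 h) and the spatial
#' window (default 0.025 degrees, roughly 2.5 km). Among candidate station
#' records the nearest in space wins; ties are broken by the smaller time
#' gap, then by the lower station id. Negative AOD retrievals are physically
#' invalid and dropped before matching.
#'
#' @param aod_records Data frame with columns `lon`, `lat`, `timestamp`
#'   (POSIXct or parseable), `aod`.
#' @param station_records Data frame with columns `station_id`, `lon`, `lat`,
#'   `timestamp`, `pm25`.
#' @param max_dt_hours Temporal half-window in hours (default 0.75).
#' @param max_dist_deg Spatial window in degrees (default 0.025); Euclidean
#'   distance in degrees, adequate at this scale.
#' @return Data frame of class `collocated_pairs` with columns `aod`, `pm25`,
#'   `timestamp`, `lon`, `lat`, `station_id`, `dt_hours`, `dist_deg`,
#'   `season` (0 = October-March, 1 = April-September) and placeholder
#'   columns `f1`, `f2` (`NA` until [attach_factor_scores()] is applied).
#' @export
collocate <- function(aod_records, station_records,
                      max_dt_hours = 0.75, max_dist_deg = 0.025) {
  assert_columns(aod_records, c("lon", "lat", "timestamp", "aod"),
                 "aod_records")
  assert_columns(station_records,
                 c("station_id", "lon", "lat", "timestamp", "pm25"),
                 "station_records")
  if (!nrow(aod_records) || !nrow(station_records))
    stop_dl("both input tables must be non-empty")
  if (max_dt_hours <= 0 || max_dist_deg <= 0)
    stop_dl("collocation windows must be positive")
  for (tab in list(aod = aod_records, station = station_records)) {
    bad <- which(is.na(tab$lon) | is.na(tab$lat) | is.na(tab$timestamp))
    if (length(bad))
      stop_dl(sprintf("missing coordinate/timestamp fields in rows: %s",
                      paste(utils::head(bad, 10), collapse = ", ")))
  }
  aod <- aod_records[aod_records$aod >= 0, , drop = FALSE]
  if (!nrow(aod)) stop_dl("no non-negative AOD retrievals to collocate")
  at <- as.numeric(as.POSIXct(aod$timestamp, tz = "UTC"))
  st <- as.numeric(as.POSIXct(station_records$timestamp, tz = "UTC"))
  ord <- order(st)
  stn <- station_records[ord, , drop = FALSE]
  st <- st[ord]
  dt_max <- max_dt_hours * 3600

  res <- vector("list", nrow(aod))
  for (i in seq_len(nrow(aod))) {
    lo <- findInterval(at[i] - dt_max, st) + 1L
    hi <- findInterval(at[i] + dt_max, st)
    if (lo > hi) next
    cand <- lo:hi
    dt <- abs(st[cand] - at[i]) / 3600
    keep <- dt <= max_dt_hours
    if (!any(keep)) next
    cand <- cand[keep]; dt <- dt[keep]
    dd <- dist_deg(aod$lon[i], aod$lat[i], stn$lon[cand], stn$lat[cand])
    keep <- dd <= max_dist_deg
    if (!any(keep)) next
    cand <- cand[keep]; dt <- dt[keep]; dd <- dd[keep]
    # sub-millimetre / sub-millisecond differences are ties, not wins
    o <- order(round(dd, 9), round(dt, 9), stn$station_id[cand])[1L]
    res[[i]] <- data.frame(
      aod = aod$aod[i], pm25 = stn$pm25[cand[o]],
      timestamp = as.POSIXct(aod$timestamp[i], tz = "UTC"),
      lon = aod$lon[i], lat = aod$lat[i],
      station_id = stn$station_id[cand[o]],
      dt_hours = dt[o], dist_deg = dd[o]
    )
  }
  res <- res[!vapply(res, is.null, logical(1))]
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(aod = numeric(), pm25 = numeric(),
               timestamp = as.POSIXct(character(), tz = "UTC"),
               lon = numeric(), lat = numeric(), station_id = numeric(),
               dt_hours = numeric(), dist_deg = numeric())
  out$season <- if (nrow(out)) season_indicator(as.Date(out$timestamp)) else
    integer()
  out$f1 <- rep(NA_real_, nrow(out))
  out$f2 <- rep(NA_real_, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("collocated_pairs", class(out))
  out
}

#' Two-factor principal-component summary of meteorological conditions
#'
#' Extracts the top two components of the correlation matrix of the seven
#' hourly meteorological variables (principal-component factoring, no
#' rotation). Loadings are the eigenvectors scaled by the square root of
#' their eigenvalues; factor scores are standardized to mean 0, sd 1.
#'
#' @param met_table Data frame containing the seven variables named in
#'   `variables` (extra columns such as `timestamp` are carried through to
#'   scoring but ignored for fitting). At least 3 complete rows are required
#'   and no variable may be constant.
#' @param variables Character vector of the seven variable names.
#' @return Object of class `met_factor_model`: `loadings` (7 x 2),
#'   `uniqueness`, `variance_explained` (percent, descending), `center`,
#'   `scale`, `rotation` (eigenvectors), `eigenvalues`.
#' @export
fit_factors <- function(met_table,
                        variables = c("wind_speed", "ceiling_height",
                                      "visibility", "dry_bulb_temp",
                                      "dew_point", "sea_level_pressure",
                                      "relative_humidity")) {
  assert_columns(met_table, variables, "met_table")
  X <- as.matrix(met_table[, variables])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3) stop_dl("need at least 3 complete meteorology rows")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop_dl("constant meteorological variable(s): ",
            paste(variables[sds == 0], collapse = ", "))
  ctr <- colMeans(X)
  Z <- scale(X, center = ctr, scale = sds)
  R <- stats::cor(Z)
  e <- eigen(R, symmetric = TRUE)
  V <- e$vectors[, 1:2, drop = FALSE]
  # sign convention: dominant loading positive
  for (j in 1:2) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  lam <- e$values[1:2]
  loadings <- V %*% diag(sqrt(lam))
  dimnames(loadings) <- list(variables, c("factor1", "factor2"))
  structure(list(
    loadings = loadings,
    uniqueness = 1 - rowSums(loadings^2),
    variance_explained = 100 * lam / length(variables),
    center = ctr, scale = sds, rotation = V, eigenvalues = lam,
    n_obs = nrow(X), variables = variables,
    method = "principal components of the correlation matrix, unrotated"
  ), class = "met_factor_model")
}

#' Score meteorology rows on a fitted factor model
#'
#' @param model A `met_factor_model` from [fit_factors()].
#' @param met_table Data frame containing the model's variables; a
#'   `timestamp` column, when present, is carried through.
#' @return Data frame with columns `f1`, `f2` (standardized scores) plus
#'   `timestamp` when available.
#' @export
score_factors <- function(model, met_table) {
  stopifnot(inherits(model, "met_factor_model"))
  assert_columns(met_table, model$variables, "met_table")
  Z <- scale(as.matrix(met_table[, model$variables]),
             center = model$center, scale = model$scale)
  S <- Z %*% model$rotation
  S <- sweep(S, 2, sqrt(model$eigenvalues), "/") # unit-variance scores
  out <- data.frame(f1 = S[, 1], f2 = S[, 2])
  if ("timestamp" %in% names(met_table)) out$timestamp <- met_table$timestamp
  out
}

#' Attach factor scores to collocated pairs
#'
#' Joins each pair to the nearest-in-time factor-score row (within
#' `max_gap_hours`), filling the `f1`/`f2` columns used by
#' [fit_calibration()].
#'
#' @param pairs A `collocated_pairs` data frame.
#' @param scores Data frame with `timestamp`, `f1`, `f2`
#'   (from [score_factors()]).
#' @param max_gap_hours Maximum tolerated time gap (default 1.5 h).
#' @return `pairs` with `f1`, `f2` filled (`NA` beyond the gap).
#' @export
attach_factor_scores <- function(pairs, scores, max_gap_hours = 1.5) {
  assert_columns(scores, c("timestamp", "f1", "f2"), "scores")
  pt <- as.numeric(as.POSIXct(pairs$timestamp, tz = "UTC"))
  stt <- as.numeric(as.POSIXct(scores$timestamp, tz = "UTC"))
  ord <- order(stt)
  stt <- stt[ord]; sc <- scores[ord, , drop = FALSE]
  idx <- findInterval(pt, stt)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(stt))
  use <- ifelse(abs(stt[lo] - pt) <= abs(stt[hi] - pt), lo, hi)
  gap <- abs(stt[use] - pt) / 3600
  ok <- gap <= max_gap_hours
  pairs$f1 <- ifelse(ok, sc$f1[use], NA_real_)
  pairs$f2 <- ifelse(ok, sc$f2[use], NA_real_)
  pairs
}

#' Fit the empirical AOD to PM2.5 calibration regression
#'
#' Ordinary least squares of ground PM2.5 on AOD, the April-September season
#' indicator and the two meteorological factor scores, with 95% confidence
#' intervals built from heteroskedasticity-robust (HC1) standard errors.
#' The AOD slope is the headline quantity: micrograms per cubic metre of
#' PM2.5 per unit AOD.
#'
#' @param pairs A `collocated_pairs` data frame (or any data frame with
#'   columns `pm25` plus the requested `terms`).
#' @param terms Regressors to include (default `c("aod", "season", "f1",
#'   "f2")`); an intercept is always included.
#' @param min_pairs Minimum number of complete pairs (default 20).
#' @return Object of class `aod_calibration`: `coefficients` (named, incl.
#'   `(Intercept)`), `se_robust`, `ci95` (matrix), `r_squared`, `n_obs`,
#'   `terms`, `vcov_robust`, and the underlying `lm` fit.
#' @export
fit_calibration <- function(pairs, terms = c("aod", "season", "f1", "f2"),
                            min_pairs = 20) {
  assert_columns(pairs, c("pm25", terms), "pairs")
  dat <- pairs[stats::complete.cases(pairs[, c("pm25", terms)]), , drop = FALSE]
  k <- length(terms) + 1L
  if (nrow(dat) < max(min_pairs, k + 1L))
    stop_dl(sprintf("need at least %d complete pairs, have %d",
                    max(min_pairs, k + 1L), nrow(dat)))
  f <- stats::reformulate(terms, response = "pm25")
  X <- stats::model.matrix(f, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_dl("rank-deficient design; collinear column(s): ",
            paste(drop_cols, collapse = ", "))
  }
  fit <- stats::lm(f, data = dat)
  V <- sandwich::vcovHC(fit, type = "HC1")
  se <- sqrt(diag(V))
  cf <- stats::coef(fit)
  tq <- stats::qt(0.975, df = nrow(dat) - k)
  ci <- cbind(lower = cf - tq * se, upper = cf + tq * se)
  structure(list(
    coefficients = cf, se_robust = se, ci95 = ci,
    # suppressWarnings: noise-free inputs trigger lm's perfect-fit notice,
    # but only the R-squared is read from the summary
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n_obs = nrow(dat), terms = terms, vcov_robust = V, fit = fit
  ), class = "aod_calibration")
}

#' @export
print.aod_calibration <- function(x, ...) {
  cat("AOD -> PM2.5 calibration (OLS, HC1-robust 95% CI)\n")
  tab <- cbind(estimate = x$coefficients, x$ci95)
  print(round(tab, 3))
  cat(sprintf("n = %d, R-squared = %.3f\n", x$n_obs, x$r_squared))
  invisible(x)
}

#' Predict PM2.5 from a fitted calibration model
#'
#' Evaluates the linear predictor. Negative predictions are physically
#' impossible concentrations; they are returned untruncated, flagged through
#' the `"negative"` attribute, and a warning is raised.
#'
#' @param model An `aod_calibration` object.
#' @param aod,season,f1,f2 Regressor values (recycled to common length).
#'   Terms not present in the model are ignored.
#' @return Numeric vector of predicted PM2.5 (micrograms per cubic metre)
#'   with a logical attribute `"negative"`.
#' @export
predict_pm25 <- function(model, aod, season = 0, f1 = 0, f2 = 0) {
  if (!inherits(model, "aod_calibration"))
    stop_dl("model must be a fitted aod_calibration object")
  vals <- list(aod = aod, season = season, f1 = f1, f2 = f2)
  n <- max(lengths(vals))
  pred <- rep(model$coefficients[["(Intercept)"]], n)
  for (term in model$terms)
    pred <- pred + model$coefficients[[term]] * rep_len(vals[[term]], n)
  neg <- pred < 0
  if (any(neg))
    warning(sum(neg), " negative PM2.5 prediction(s); returned untruncated")
  attr(pred, "negative") <- neg
  pred
}
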