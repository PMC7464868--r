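# Case/control analysis frame and cluster-robust logistic risk models.
#
# Rows are person-events: one row per AECOPD event (outcome 1) or per
# control clinic visit (outcome 0); within-subject correlation across a
# subject's multiple events is handled by the cluster-robust covariance.

BASE_COVARIATES <- c("age", "asthma", "smoking_active", "fev1_fvc")

#' Assemble the case/control analysis frame
#'
#' Case rows are the event days of subjects with at least `min_events`
#' events who reside inside the catchment box; control rows are the
#' clinic-visit days of zero-event subjects in the catchment. Lag-1 PM2.5
#' and temperature come from the exposure series; dust variables from the
#' lag table. Rows with missing lag-1 PM2.5 (satellite gaps) are marked
#' `complete = FALSE` and are dropped only from models containing PM2.5.
#'
#' @param roster Data frame with one row per index date: `subject_id`,
#'   `lon`, `lat`, `age`, `asthma`, `smoking_active`, `fev1_fvc`,
#'   `index_date`, `event` (1 = AECOPD event day, 0 = control visit).
#' @param lags Lag table from [build_lag_table()], or `NULL` to omit dust
#'   variables.
#' @param exposures Exposure series from [build_exposure_series()] (or
#'   [truth_exposure_series()]), or `NULL` to omit PM2.5/temperature.
#' @param min_events Minimum events for a subject's event days to enter as
#'   cases (1 keeps all events; the study analyses use 2 and 3).
#' @param catchment Bounding box (see [catchment_box()]).
#' @param intensity_scale Depolarization-ratio units per dust-intensity
#'   model unit (default 0.1): the model covariates `dust1_intensity` and
#'   `dust_dist15` are the raw depolarization quantities divided by this,
#'   so a typical dust day (ratio ~0.15) scores ~1.5 units and odds ratios
#'   are comparable with the binary dust contrast.
#' @param L_dist Look-back length of the distributed-lag covariate carried
#'   into the frame (default 15).
#' @return Data frame of class `analysis_frame` with columns `subject_id`,
#'   `index_date`, `outcome`, the four adjustment covariates,
#'   `pm25_lag1`, `temp_lag1`, `dust1_binary`, `dust1_intensity`,
#'   `dust_dist15`, `complete`.
#' @export
assemble_frame <- function(roster, lags = NULL, exposures = NULL,
                           min_events = 2, catchment = catchment_box(),
                           intensity_scale = 0.1, L_dist = 15) {
  assert_columns(roster, c("subject_id", "lon", "lat", "index_date",
                           "event"), "roster")
  ros <- roster
  ros$index_date <- as_date_strict(ros$index_date, "index_date")
  ros <- ros[in_box(ros$lon, ros$lat, catchment), , drop = FALSE]
  n_ev <- tapply(ros$event, ros$subject_id, sum)
  ros$n_events <- as.numeric(n_ev[as.character(ros$subject_id)])
  cases <- ros[ros$event == 1 & ros$n_events >= min_events, , drop = FALSE]
  controls <- ros[ros$event == 0 & ros$n_events == 0, , drop = FALSE]
  if (!nrow(cases) || !nrow(controls))
    stop_dl(sprintf(
      "frame is empty after filtering: %d case rows, %d control rows",
      nrow(cases), nrow(controls)))
  frame <- rbind(cases, controls)
  frame$outcome <- frame$event
  keep <- c("subject_id", "index_date", "outcome",
            intersect(BASE_COVARIATES, names(frame)))
  frame <- frame[, keep]
  key <- function(df) paste(df$subject_id, as.integer(df$index_date))
  fk <- key(frame)

  frame$pm25_lag1 <- NA_real_
  frame$temp_lag1 <- NA_real_
  if (!is.null(exposures)) {
    e1 <- exposures[exposures$lag == 1, , drop = FALSE]
    pos <- match(fk, key(e1))
    frame$pm25_lag1 <- e1$pm25[pos]
    frame$temp_lag1 <- e1$temperature[pos]
  }
  frame$dust1_binary <- NA_real_
  frame$dust1_intensity <- NA_real_
  frame$dust_dist15 <- NA_real_
  if (!is.null(lags)) {
    l1 <- lags[lags$lag == 1, , drop = FALSE]
    pos <- match(fk, key(l1))
    frame$dust1_binary <- as.numeric(l1$x_binary[pos])
    frame$dust1_intensity <- l1$x_intensity[pos] / intensity_scale
    lD <- lags[lags$lag == L_dist, , drop = FALSE]
    pos <- match(fk, key(lD))
    frame$dust_dist15 <- lD$x_distributed[pos] / intensity_scale
  }
  frame$complete <- !is.na(frame$pm25_lag1)
  rownames(frame) <- NULL
  class(frame) <- c("analysis_frame", class(frame))
  frame
}

# IRLS fit of a logistic regression; returns beta, final weights, fitted
# probabilities and the log-likelihood trace.
irls_logit <- function(X, y, tol = 1e-10, max_iter = 100) {
  beta <- numeric(ncol(X))
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    ll <- sum(ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
                     stats::plogis(-eta, log.p = TRUE)))
    ll_trace <- c(ll_trace, ll)
    w <- pmax(p * (1 - p), 1e-12)
    z <- eta + (y - p) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new))
      stop_dl("singular weighted design during IRLS")
    beta <- drop(beta_new)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 0.1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  list(beta = beta, p = p, w = pmax(p * (1 - p), 1e-12),
       loglik = ll_trace, converged = converged)
}

#' Cluster-robust logistic regression
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares,
#' with a sandwich covariance summing score contributions within clusters:
#' \deqn{V = c\,(X'WX)^{-1}\Big(\sum_g s_g s_g'\Big)(X'WX)^{-1},\quad
#'       c = \frac{G}{G-1}\cdot\frac{N-1}{N-k},}
#' where \eqn{s_g} is the summed score of cluster \eqn{g} -- the
#' finite-sample convention of Stata's `vce(cluster)`. Odds ratios and Wald
#' 95% intervals (z = 1.96) are reported on the exponentiated scale.
#'
#' @param data Data frame containing the model variables and the cluster id.
#' @param formula Model formula, e.g. `outcome ~ age + dust1_intensity`.
#' @param cluster Name of the cluster-id column (default `"subject_id"`).
#' @param tol,max_iter IRLS convergence control: relative log-likelihood
#'   change below `tol` (default 1e-10) within `max_iter` (default 100)
#'   iterations.
#' @return Object of class `cluster_logit`: `coef`, `robust_cov`, `se`,
#'   `or_`, `ci95` (matrix on the OR scale), `n_obs`, `n_clusters`,
#'   `converged`, `loglik` (IRLS trace), `formula`.
#' @export
fit_logit_cluster <- function(data, formula, cluster = "subject_id",
                              tol = 1e-10, max_iter = 100) {
  if (is.null(data[[cluster]]))
    stop_dl("cluster column '", cluster, "' not found")
  vars <- all.vars(formula)
  assert_columns(data, vars, "model data")
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  dat <- data[keep, , drop = FALSE]
  mf <- stats::model.frame(formula, data = dat)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  cl <- dat[[cluster]]
  if (length(unique(cl)) < 2) stop_dl("need at least 2 clusters")
  if (length(unique(y)) < 2)
    stop_dl("outcome must contain both classes")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_dl("rank-deficient design; collinear column(s): ",
            paste(bad, collapse = ", "))
  }
  fit <- irls_logit(X, y, tol = tol, max_iter = max_iter)
  # separation check: coefficient diverging on the standardized scale
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  std_beta <- abs(fit$beta) * sds
  is_icpt <- colnames(X) == "(Intercept)"
  diverged <- (std_beta > 10 & !is_icpt) | abs(fit$beta) > 1e4
  if (any(diverged))
    stop_dl("separation detected for covariate(s): ",
            paste(colnames(X)[diverged], collapse = ", "))
  if (!fit$converged)
    warning("IRLS did not converge within ", max_iter, " iterations")

  N <- nrow(X); k <- ncol(X); G <- length(unique(cl))
  bread <- solve(t(X * fit$w) %*% X)
  S <- X * (y - fit$p)                       # per-row scores
  Sg <- rowsum(S, group = cl)                # cluster score sums
  meat <- crossprod(Sg)
  cfac <- (G / (G - 1)) * ((N - 1) / (N - k))
  V <- cfac * bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(V))
  beta <- stats::setNames(fit$beta, colnames(X))
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  structure(list(
    coef = beta, robust_cov = V, se = se, or_ = exp(beta), ci95 = ci,
    n_obs = N, n_clusters = G, converged = fit$converged,
    loglik = fit$loglik, formula = formula,
    small_sample_factor = cfac
  ), class = "cluster_logit")
}

#' @export
print.cluster_logit <- function(x, ...) {
  cat("Cluster-robust logistic fit:",
      deparse(x$formula), "\n")
  z <- x$coef / x$se
  p <- 2 * stats::pnorm(-abs(z))
  stars <- ifelse(p < 0.01, "***", ifelse(p < 0.05, "**",
                  ifelse(p < 0.1, "*", "")))
  tab <- data.frame(OR = round(x$or_, 3),
                    lower = round(x$ci95[, "lower"], 3),
                    upper = round(x$ci95[, "upper"], 3),
                    p = signif(p, 3), sig = stars)
  print(tab)
  cat(sprintf("n = %d observations in %d clusters\n",
              x$n_obs, x$n_clusters))
  invisible(x)
}

#' Coefficients of a cluster-robust logistic fit
#' @param object A `cluster_logit` object.
#' @param ... Unused.
#' @export
coef.cluster_logit <- function(object, ...) object$coef

#' Robust covariance of a cluster-robust logistic fit
#' @param object A `cluster_logit` object.
#' @param ... Unused.
#' @export
vcov.cluster_logit <- function(object, ...) object$robust_cov

model_suite_terms <- function() {
  list(m1 = c(BASE_COVARIATES, "pm25_lag1"),
       m2 = c(BASE_COVARIATES, "temp_lag1"),
       m3 = c(BASE_COVARIATES, "dust1_intensity"),
       m4 = c(BASE_COVARIATES, "pm25_lag1", "temp_lag1"),
       m5 = c(BASE_COVARIATES, "temp_lag1", "dust1_intensity"),
       m6 = c(BASE_COVARIATES, "pm25_lag1", "temp_lag1",
              "dust1_intensity"))
}

#' Fit the six adjusted risk models
#'
#' All models adjust for age, asthma, smoking status and lung function
#' (FEV1/FVC); they add, respectively: (1) lag-1 PM2.5; (2) lag-1 ambient
#' temperature; (3) lag-1 dust intensity; (4) PM2.5 + temperature;
#' (5) temperature + dust; (6) all three exposures. Models containing PM2.5
#' are restricted to complete rows (no satellite gap at lag 1).
#'
#' @param frame An `analysis_frame` from [assemble_frame()].
#' @param models Integer subset of 1:6 (default all).
#' @return Named list (`m1`..`m6`) of `cluster_logit` fits.
#' @export
run_model_suite <- function(frame, models = 1:6) {
  specs <- model_suite_terms()[models]
  out <- lapply(names(specs), function(nm) {
    terms <- specs[[nm]]
    dat <- if ("pm25_lag1" %in% terms)
      frame[frame$complete, , drop = FALSE] else frame
    fit_logit_cluster(dat, stats::reformulate(terms, response = "outcome"))
  })
  stats::setNames(out, names(specs))
}

#' Odds-ratio table for a list of fits
#'
#' @param fits Named list of `cluster_logit` objects (e.g. from
#'   [run_model_suite()]).
#' @return Data frame with one row per model and term: OR, 95% CI bounds,
#'   p-value and significance stars at 0.01/0.05/0.1.
#' @export
model_suite_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    z <- f$coef / f$se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(model = nm, term = names(f$coef), or = unname(f$or_),
               lower = unname(f$ci95[, "lower"]),
               upper = unname(f$ci95[, "upper"]), p = unname(p),
               sig = ifelse(p < 0.01, "***", ifelse(p < 0.05, "**",
                            ifelse(p < 0.1, "*", ""))),
               n_obs = f$n_obs, row.names = NULL)
  }))
}

#' Lag sweep of dust-exposure odds ratios
#'
#' One cluster-robust logistic fit per lag 0..15 for the requested exposure
#' conceptualisation: `binary` (dust day yes/no on the lagged day),
#' `intensity` (depolarization on the lagged day, in model units), or
#' `distributed` (the inverse-time-weighted cumulative statistic over lags
#' 1..L). Covariates follow Model 3 (age, asthma, smoking, lung function).
#' Cells where the fit is inestimable -- constant exposure, separation, or
#' a singular design -- are reported as `NA` rather than dropped.
#'
#' @param frame An `analysis_frame` (provides outcome, covariates and the
#'   subject/index keys).
#' @param lag_table Lag table from [build_lag_table()].
#' @param lags Integer lags to fit (default 0:15).
#' @param kind One of `"binary"`, `"intensity"`, `"distributed"`.
#' @param intensity_scale Depolarization units per model unit (default 0.1;
#'   must match the frame's scale).
#' @return Data frame with columns `lag`, `or`, `lower`, `upper`, `p`,
#'   `n_obs`, `note` (empty or the failure reason).
#' @export
lag_sweep <- function(frame, lag_table, lags = 0:15,
                      kind = c("distributed", "intensity", "binary"),
                      intensity_scale = 0.1) {
  kind <- match.arg(kind)
  var <- switch(kind, binary = "x_binary", intensity = "x_intensity",
                distributed = "x_distributed")
  key <- function(df) paste(df$subject_id, as.integer(df$index_date))
  fk <- key(frame)
  out <- vector("list", length(lags))
  for (i in seq_along(lags)) {
    l <- lags[i]
    lt <- lag_table[lag_table$lag == l, , drop = FALSE]
    x <- lt[[var]][match(fk, key(lt))]
    if (kind != "binary") x <- x / intensity_scale
    dat <- frame
    dat$x_dust <- x
    fit <- tryCatch(
      fit_logit_cluster(dat, stats::reformulate(
        c(BASE_COVARIATES, "x_dust"), response = "outcome")),
      error = function(e) e)
    if (inherits(fit, "error")) {
      out[[i]] <- data.frame(lag = l, or = NA_real_, lower = NA_real_,
                             upper = NA_real_, p = NA_real_,
                             n_obs = NA_integer_,
                             note = conditionMessage(fit))
    } else {
      z <- fit$coef[["x_dust"]] / fit$se[["x_dust"]]
      out[[i]] <- data.frame(
        lag = l, or = fit$or_[["x_dust"]],
        lower = fit$ci95["x_dust", "lower"],
        upper = fit$ci95["x_dust", "upper"],
        p = 2 * stats::pnorm(-abs(z)), n_obs = fit$n_obs, note = "")
    }
  }
  do.call(rbind, out)
}
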