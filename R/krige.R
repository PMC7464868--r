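# Local space-time ordinary kriging of daily fields (PM2.5, temperature) to
# subject residences, with an inverse-distance-weighting fallback.
#
# Time is folded into the spatial metric through an anisotropy ratio
# (degrees per day): d = sqrt(dist_deg^2 + (anisotropy * delta_days)^2).

#' Default kriging parameters
#'
#' @param spatial_radius Neighborhood radius in degrees (default 0.5).
#' @param temporal_window Neighborhood half-width in days (default 3).
#' @param anisotropy Degrees-per-day conversion of time to space
#'   (default 0.1).
#' @param min_neighbors Minimum neighbors for a kriging solve (default 4);
#'   fewer (but at least one) triggers the IDW fallback.
#' @param max_neighbors Neighbors retained, nearest first (default 50).
#' @param n_bins Distance bins for the empirical variogram (default 12).
#' @param nugget,sill,range Fixed exponential-variogram parameters; any
#'   `NULL` entry is fitted from the data by weighted least squares.
#' @return A list of class `krige_params`.
#' @export
krige_params <- function(spatial_radius = 0.5, temporal_window = 3,
                         anisotropy = 0.1, min_neighbors = 4,
                         max_neighbors = 50, n_bins = 12,
                         nugget = NULL, sill = NULL, range = NULL) {
  if (spatial_radius <= 0 || temporal_window <= 0 || anisotropy <= 0)
    stop_dl("radii and anisotropy must be positive")
  if (min_neighbors < 3) stop_dl("min_neighbors must be at least 3")
  if (!is.null(nugget) && nugget < 0) stop_dl("nugget must be non-negative")
  if (!is.null(nugget) && !is.null(sill) && sill <= nugget)
    stop_dl("sill must exceed nugget")
  structure(list(spatial_radius = spatial_radius,
                 temporal_window = temporal_window,
                 anisotropy = anisotropy, min_neighbors = min_neighbors,
                 max_neighbors = max_neighbors, n_bins = n_bins,
                 nugget = nugget, sill = sill, range = range),
            class = "krige_params")
}

st_distance <- function(lon1, lat1, day1, lon2, lat2, day2, anisotropy) {
  dd <- as.numeric(as.Date(day1)) - as.numeric(as.Date(day2))
  sqrt((lon1 - lon2)^2 + (lat1 - lat2)^2 + (anisotropy * dd)^2)
}

exp_variogram <- function(h, nugget, sill, range) {
  ifelse(h <= 0, 0, nugget + (sill - nugget) * (1 - exp(-h / range)))
}

#' Empirical space-time semivariogram
#'
#' Bins all point pairs by the combined space-time distance and returns the
#' mean squared half-difference per bin. Bins containing no pairs are
#' omitted.
#'
#' @param points Data frame with columns `lon`, `lat`, `day`, `value`.
#' @param params A [krige_params()] list (anisotropy and `n_bins` are used).
#' @return Data frame with columns `dist` (mean pair distance in the bin),
#'   `gamma` (semivariance) and `npairs`.
#' @export
empirical_variogram <- function(points, params = krige_params()) {
  assert_columns(points, c("lon", "lat", "day", "value"), "points")
  n <- nrow(points)
  if (n < params$min_neighbors)
    stop_dl("need at least min_neighbors points")
  day <- as.numeric(as.Date(points$day))
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  h <- sqrt((points$lon[ii] - points$lon[jj])^2 +
            (points$lat[ii] - points$lat[jj])^2 +
            (params$anisotropy * (day[ii] - day[jj]))^2)
  if (max(h) == 0) stop_dl("all points are coincident")
  g <- 0.5 * (points$value[ii] - points$value[jj])^2
  breaks <- seq(0, max(h) * (1 + 1e-9), length.out = params$n_bins + 1L)
  bin <- cut(h, breaks, include.lowest = TRUE, labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(dist = mean(h[sel]), gamma = mean(g[sel]),
               npairs = sum(sel))
  }))
  rownames(out) <- NULL
  out
}

# WLS fit of the exponential model to an empirical variogram; returns NULL
# when the problem is degenerate or the optimiser fails.
fit_variogram_wls <- function(vg) {
  if (nrow(vg) < 3 || all(vg$gamma == 0)) return(NULL)
  s0 <- max(vg$gamma)
  r0 <- max(vg$dist) / 3
  obj <- function(p) {
    m <- exp_variogram(vg$dist, p[1], p[1] + p[2], p[3])
    sum(vg$npairs * (vg$gamma - m)^2)
  }
  fit <- tryCatch(
    stats::optim(c(0, s0, r0), obj, method = "L-BFGS-B",
                 lower = c(0, 1e-10 * max(s0, 1), 1e-6 * max(r0, 1)),
                 upper = c(s0, 10 * s0, 100 * r0)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) return(NULL)
  list(nugget = fit$par[1], sill = fit$par[1] + fit$par[2],
       range = fit$par[3])
}

resolve_variogram <- function(points, params) {
  fixed <- params[c("nugget", "sill", "range")]
  if (!any(vapply(fixed, is.null, logical(1)))) return(fixed)
  vg <- tryCatch(empirical_variogram(points, params),
                 error = function(e) NULL)
  est <- if (!is.null(vg)) fit_variogram_wls(vg) else NULL
  if (is.null(est)) { # global fallback when the local fit is ill-conditioned
    v <- stats::var(points$value)
    est <- list(nugget = 0, sill = max(v, 1e-10),
                range = max(params$spatial_radius / 3, 1e-6))
  }
  list(nugget = fixed$nugget %||% est$nugget,
       sill = fixed$sill %||% est$sill,
       range = fixed$range %||% est$range)
}

#' Ordinary kriging prediction at a space-time target
#'
#' Predicts the field at one location/day from neighbors inside the local
#' space-time window using ordinary kriging (weights constrained to sum to
#' one) under an exponential variogram. When fewer than `min_neighbors`
#' neighbors exist, or the kriging system cannot be solved, the estimate
#' falls back to inverse-distance weighting (power 2 on the combined
#' metric), recorded in the `method` field. With no neighbors at all the
#' output is an explicit missing value, never a silent zero.
#'
#' @param points Data frame with columns `lon`, `lat`, `day`, `value`.
#'   Duplicate space-time locations are averaged before solving.
#' @param target List or one-row data frame with `lon`, `lat`, `day`.
#' @param params A [krige_params()] list; fixing `nugget`, `sill` and
#'   `range` skips variogram fitting.
#' @return List: `estimate`, `variance` (kriging variance; `NA` under IDW),
#'   `method` (`"krige"`, `"idw"` or `"missing"`), `n_neighbors`, `weights`,
#'   and `neighbors` (the neighbor rows the weights refer to, nearest
#'   first).
#' @export
krige_predict <- function(points, target, params = krige_params()) {
  assert_columns(points, c("lon", "lat", "day", "value"), "points")
  pts <- stats::aggregate(value ~ lon + lat + day, data = points, FUN = mean)
  d0 <- st_distance(pts$lon, pts$lat, pts$day,
                    target$lon, target$lat, target$day, params$anisotropy)
  ds <- dist_deg(pts$lon, pts$lat, target$lon, target$lat)
  dt <- abs(as.numeric(as.Date(pts$day)) - as.numeric(as.Date(target$day)))
  sel <- which(ds <= params$spatial_radius & dt <= params$temporal_window)
  if (!length(sel))
    return(list(estimate = NA_real_, variance = NA_real_,
                method = "missing", n_neighbors = 0L, weights = numeric(),
                neighbors = pts[integer(), ]))
  sel <- sel[order(d0[sel])]
  if (length(sel) > params$max_neighbors)
    sel <- sel[seq_len(params$max_neighbors)]
  nb <- pts[sel, , drop = FALSE]
  d0 <- d0[sel]
  n <- nrow(nb)

  idw <- function() {
    if (any(d0 < 1e-12))
      return(list(estimate = mean(nb$value[d0 < 1e-12]),
                  variance = NA_real_, method = "idw",
                  n_neighbors = n, weights = as.numeric(d0 < 1e-12),
                  neighbors = nb))
    w <- 1 / d0^2; w <- w / sum(w)
    list(estimate = sum(w * nb$value), variance = NA_real_,
         method = "idw", n_neighbors = n, weights = w, neighbors = nb)
  }
  if (n < params$min_neighbors) return(idw())

  vgm <- resolve_variogram(nb, params)
  # exact interpolation shortcut: zero nugget and a coincident observation
  if (vgm$nugget == 0 && any(d0 < 1e-12)) {
    w <- as.numeric(d0 < 1e-12); w <- w / sum(w)
    return(list(estimate = sum(w * nb$value), variance = 0,
                method = "krige", n_neighbors = n, weights = w,
                neighbors = nb))
  }
  day_n <- nb$day
  H <- outer(seq_len(n), seq_len(n), function(i, j)
    st_distance(nb$lon[i], nb$lat[i], day_n[i],
                nb$lon[j], nb$lat[j], day_n[j], params$anisotropy))
  G <- rbind(cbind(exp_variogram(H, vgm$nugget, vgm$sill, vgm$range), 1),
             c(rep(1, n), 0))
  g0 <- c(exp_variogram(d0, vgm$nugget, vgm$sill, vgm$range), 1)
  sol <- tryCatch(solve(G, g0), error = function(e) NULL)
  if (is.null(sol) || anyNA(sol)) return(idw())
  w <- sol[seq_len(n)]
  lambda <- sol[n + 1L]
  list(estimate = sum(w * nb$value),
       variance = max(sum(w * g0[seq_len(n)]) + lambda, 0),
       method = "krige", n_neighbors = n, weights = w, neighbors = nb)
}

#' Interpolated exposure series for each subject and lag day
#'
#' For every subject index date (event date for cases, clinic-visit date for
#' controls) interpolates daily PM2.5 and ambient temperature at the
#' residence for lags 0..`L_max`. Days with no neighbors are marked missing
#' and the `pm25_source` column records whether each PM2.5 value came from
#' kriging, the IDW fallback, or is missing; missingness propagates to the
#' model frame. Subjects outside the field extent are flagged with a warning
#' but their series is still attempted.
#'
#' @param roster Data frame with columns `subject_id`, `lon`, `lat`,
#'   `index_date` (one row per index date).
#' @param pm25_points Data frame of daily PM2.5 field points (`lon`, `lat`,
#'   `day`, `value`); multiple values per location/day (e.g. two satellite
#'   overpasses) are averaged.
#' @param temp_points Daily temperature points in the same format, or `NULL`
#'   to skip temperature.
#' @param params A [krige_params()] list.
#' @param L_max Maximum lag in days (default 15).
#' @return Data frame with columns `subject_id`, `index_date`, `lag`,
#'   `date`, `pm25`, `pm25_source`, `temperature`.
#' @export
build_exposure_series <- function(roster, pm25_points, temp_points = NULL,
                                  params = krige_params(), L_max = 15) {
  assert_columns(roster, c("subject_id", "lon", "lat", "index_date"),
                 "roster")
  assert_columns(pm25_points, c("lon", "lat", "day", "value"), "pm25_points")
  idx <- unique(roster[, c("subject_id", "lon", "lat", "index_date")])
  idx$index_date <- as_date_strict(idx$index_date, "index_date")
  ext <- list(lon = range(pm25_points$lon), lat = range(pm25_points$lat))
  outside <- !in_box(idx$lon, idx$lat, ext)
  if (any(outside))
    warning(sum(outside), " subject(s) outside the field extent; ",
            "series attempted anyway")
  pm25_points$day <- as_date_strict(pm25_points$day, "pm25 day")
  if (!is.null(temp_points))
    temp_points$day <- as_date_strict(temp_points$day, "temperature day")
  rows <- vector("list", nrow(idx) * (L_max + 1L))
  k <- 0L
  for (i in seq_len(nrow(idx))) {
    for (l in 0:L_max) {
      day <- idx$index_date[i] - l
      tgt <- list(lon = idx$lon[i], lat = idx$lat[i], day = day)
      sub <- pm25_points[abs(as.numeric(pm25_points$day - day)) <=
                           params$temporal_window, , drop = FALSE]
      pm <- if (nrow(sub)) krige_predict(sub, tgt, params) else
        list(estimate = NA_real_, method = "missing")
      tmp <- NA_real_
      if (!is.null(temp_points)) {
        subt <- temp_points[abs(as.numeric(temp_points$day - day)) <=
                              params$temporal_window, , drop = FALSE]
        if (nrow(subt)) tmp <- krige_predict(subt, tgt, params)$estimate
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject_id = idx$subject_id[i], index_date = idx$index_date[i],
        lag = l, date = day, pm25 = pm$estimate, pm25_source = pm$method,
        temperature = tmp)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
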