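# Synthetic study generator: environment tables (AOD, ground PM2.5,
# meteorology, LIDAR/PM10) and a cohort roster with known ground truth, so
# that every downstream stage can be validated without restricted data.

#' Configuration for the synthetic study generator
#'
#' Defaults reproduce the study conditions of the Miami dust/COPD setting:
#' 296 subjects followed daily over 2013-2016, a June-September dust season
#' with a 0.4 per-day dust probability (roughly 50 dust days a season),
#' event depolarization ratios around 0.145 against a 0.05 baseline, the
#' published AOD-to-PM2.5 calibration coefficients as generating truth, a
#' baseline event probability of 7e-4 per person-day (about 313 events among
#' 296 subjects in four years), and a grid extent leaving about 9% of
#' residences outside the catchment box.
#'
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @param n_subjects Number of cohort subjects.
#' @param n_stations Number of ground PM2.5 monitoring stations.
#' @param grid_extent Lon/lat box (list with `lon`, `lat` ranges, degrees).
#' @param date_range Character or Date vector of length 2 (start, end);
#'   at least 60 days.
#' @param true_calibration Generating calibration coefficients: `intercept`,
#'   `aod_slope` (must be positive), `season`, `factor1`, `factor2`
#'   (micrograms per cubic metre per unit) and `noise_sd`.
#' @param dust_season Integer months of the dust season (default 6:9).
#' @param dust_day_prob Probability that an in-season day is a dust day.
#' @param depol_params Depolarization draw parameters: `baseline_mean`,
#'   `baseline_sd`, `event_mean`, `event_sd` (dimensionless ratios).
#' @param true_or Named vector/list of generating odds ratios per model unit
#'   for any of `pm25` (per microgram per cubic metre), `temperature`
#'   (per degree C), `dust` (per dust-intensity unit, see
#'   `intensity_scale`), `dust_distributed` (per unit of the 15-day
#'   inverse-time-weighted statistic).
#' @param baseline_event_prob Marginal event probability per person-day;
#'   the generator anchors the hazard intercept so this rate holds under
#'   any configured effects.
#' @param subject_sd SD of the Gaussian random intercept on the log-odds
#'   scale inducing within-subject clustering (default 0.5).
#' @param aod_missing_prob Missing-at-random probability for satellite AOD
#'   (propagates to missing PM2.5 exposure; default 0.45, mirroring the
#'   share of analysis rows with computable PM2.5).
#' @param intensity_scale Depolarization units per dust-intensity model
#'   unit (default 0.1; see [assemble_frame()]).
#' @param smoking_prob,asthma_prob Covariate prevalences.
#' @param aod_per_day Random AOD retrievals generated per satellite
#'   overpass (two overpasses daily), in addition to one retrieval at each
#'   station location.
#' @param met_loadings Optional 7 x 2 matrix of generating factor loadings;
#'   the default loads temperature/dew point on factor 1 and relative
#'   humidity on factor 2.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_subjects = 296,
                         n_stations = 10,
                         grid_extent = list(lon = c(-81.1, -80),
                                            lat = c(25, 27.15)),
                         date_range = c("2013-01-01", "2016-12-31"),
                         true_calibration = list(intercept = 7.17,
                                                 aod_slope = 21.44,
                                                 season = 0.64,
                                                 factor1 = 1.85,
                                                 factor2 = -0.69,
                                                 noise_sd = 4.5),
                         dust_season = 6:9,
                         dust_day_prob = 0.4,
                         depol_params = list(baseline_mean = 0.05,
                                             baseline_sd = 0.02,
                                             event_mean = 0.145,
                                             event_sd = 0.03),
                         true_or = c(pm25 = 1.122, temperature = 1.062,
                                     dust = 4.955),
                         baseline_event_prob = 7e-4,
                         subject_sd = 0.5,
                         aod_missing_prob = 0.45,
                         intensity_scale = 0.1,
                         smoking_prob = 0.432,
                         asthma_prob = 0.111,
                         aod_per_day = 40,
                         met_loadings = NULL) {
  probs <- c(dust_day_prob = dust_day_prob,
             baseline_event_prob = baseline_event_prob,
             aod_missing_prob = aod_missing_prob,
             smoking_prob = smoking_prob, asthma_prob = asthma_prob)
  if (any(probs < 0 | probs > 1))
    stop_dl("all probabilities must lie in [0, 1]: ",
            paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (true_calibration$aod_slope <= 0) stop_dl("aod_slope must be positive")
  if (subject_sd < 0) stop_dl("subject_sd must be non-negative")
  if (intensity_scale <= 0) stop_dl("intensity_scale must be positive")
  if (diff(range(grid_extent$lon)) <= 0 || diff(range(grid_extent$lat)) <= 0)
    stop_dl("degenerate grid extent: zero area")
  d <- as_date_strict(date_range, "date_range")
  if (d[2] < d[1]) stop_dl("empty date range")
  if (as.numeric(d[2] - d[1]) + 1 < 60)
    stop_dl("date range must span at least 60 days")
  if (is.null(met_loadings)) {
    met_loadings <- cbind(
      factor1 = c(0.05, -0.05, 0.05, 0.75, 0.70, -0.20, 0.10),
      factor2 = c(-0.05, 0.05, -0.05, -0.35, 0.45, -0.05, 0.90))
    rownames(met_loadings) <- c("wind_speed", "ceiling_height", "visibility",
                                "dry_bulb_temp", "dew_point",
                                "sea_level_pressure", "relative_humidity")
  }
  structure(list(seed = as.integer(seed), n_subjects = n_subjects,
                 n_stations = n_stations, grid_extent = grid_extent,
                 date_range = d, true_calibration = true_calibration,
                 dust_season = dust_season, dust_day_prob = dust_day_prob,
                 depol_params = depol_params, true_or = true_or,
                 baseline_event_prob = baseline_event_prob,
                 subject_sd = subject_sd,
                 aod_missing_prob = aod_missing_prob,
                 intensity_scale = intensity_scale,
                 smoking_prob = smoking_prob, asthma_prob = asthma_prob,
                 aod_per_day = aod_per_day, met_loadings = met_loadings),
            class = "synth_config")
}

# smooth spatial perturbation of the AOD field (low-frequency harmonics)
aod_spatial_field <- function(lon, lat, extent) {
  u <- (lon - extent$lon[1]) / diff(range(extent$lon))
  v <- (lat - extent$lat[1]) / diff(range(extent$lat))
  0.02 * sin(2 * pi * u) + 0.015 * cos(2 * pi * v)
}

#' Generate the synthetic environmental tables
#'
#' Draws a daily environment over the configured date range -- dust days
#' inside the dust season, depolarization ratios from the event or baseline
#' distribution, PM10 elevated on dust days, a seasonal regional AOD field
#' with dust spikes, daily meteorological factor scores and temperature --
#' and, in `"full"` detail, the four observation tables: AOD retrievals,
#' hourly ground PM2.5 station records (generated by inverting the
#' calibration relationship: PM2.5 = intercept + slope x AOD + season +
#' factor terms + Gaussian noise), hourly meteorology driven by a two-factor
#' model, and the daily LIDAR/PM10 series. `"daily"` detail skips the three
#' large observation tables and keeps the daily truth scaffolding, which is
#' all the cohort generator needs.
#'
#' @param config A [synth_config()].
#' @param detail `"full"` (default) or `"daily"`.
#' @return List of class `dust_synth_env`: `daily` (truth scaffolding with
#'   date, season, dust flag, grade, depol, pm10, aod_regional, f1, f2,
#'   temp_c), `lidar`, and in full detail `aod`, `pm25`, `met`, `stations`.
#' @export
generate_environment <- function(config, detail = c("full", "daily")) {
  stopifnot(inherits(config, "synth_config"))
  detail <- match.arg(detail)
  set.seed(config$seed)
  dates <- seq(config$date_range[1], config$date_range[2], by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  month <- as.integer(format(dates, "%m"))
  dp <- config$depol_params

  in_season <- month %in% config$dust_season
  dust <- in_season & stats::runif(n) < config$dust_day_prob
  depol <- ifelse(dust,
                  stats::rnorm(n, dp$event_mean, dp$event_sd),
                  stats::rnorm(n, dp$baseline_mean, dp$baseline_sd))
  depol <- pmin(pmax(depol, 0), 1)
  pm10 <- ifelse(dust, stats::rnorm(n, 45, 8), stats::rnorm(n, 20, 5))
  pm10 <- pmax(pm10, 1)
  f1 <- stats::rnorm(n)
  f2 <- stats::rnorm(n)
  seasonal <- sin(2 * pi * (doy - 120) / 365.25)
  temp_c <- 21 + 4 * seasonal + 1.2 * f1 + stats::rnorm(n, 0, 0.8)
  aod_regional <- 0.13 + 0.04 * sin(2 * pi * (doy - 170) / 365.25) +
    ifelse(dust, stats::rnorm(n, 0.06, 0.02), 0) + stats::rnorm(n, 0, 0.015)
  aod_regional <- pmax(aod_regional, 0.02)

  daily <- data.frame(
    date = dates, season = season_indicator(dates), in_season = in_season,
    dust = dust, depol = depol,
    grade = ifelse(dust, grade_intensity(depol), "none"),
    pm10 = pm10, aod_regional = aod_regional, f1 = f1, f2 = f2,
    temp_c = temp_c)
  lidar <- data.frame(date = dates, depol = depol, pm10 = pm10)
  env <- list(daily = daily, lidar = lidar, config = config)
  class(env) <- "dust_synth_env"
  if (detail == "daily") return(env)

  ext <- config$grid_extent
  cal <- config$true_calibration
  stations <- data.frame(
    station_id = seq_len(config$n_stations),
    lon = stats::runif(config$n_stations, ext$lon[1], ext$lon[2]),
    lat = stats::runif(config$n_stations, ext$lat[1], ext$lat[2]))

  # hourly meteorology from the two-factor model (hours 0..23 UTC-5 ignored;
  # wall-clock detail is irrelevant to the daily pipeline)
  hours <- 0:23
  ts_met <- as.POSIXct(outer(as.numeric(as.POSIXct(dates, tz = "UTC")),
                             hours * 3600, "+"),
                       origin = "1970-01-01", tz = "UTC")
  ord <- order(ts_met)
  ts_met <- ts_met[ord]
  nh <- length(ts_met)
  day_of <- rep(seq_len(n), times = length(hours))[ord]
  F1h <- f1[day_of] + stats::rnorm(nh, 0, 0.5)
  F2h <- f2[day_of] + stats::rnorm(nh, 0, 0.5)
  L <- config$met_loadings
  uniq <- pmax(1 - rowSums(L^2), 0.02)
  mu <- c(4, 5000, 14000, 75, 65, 1016, 75)
  sdv <- c(2, 2500, 3000, 8, 7, 4, 8)
  met <- data.frame(timestamp = ts_met)
  for (v in seq_len(nrow(L))) {
    z <- L[v, 1] * F1h + L[v, 2] * F2h +
      sqrt(uniq[v]) * stats::rnorm(nh)
    met[[rownames(L)[v]]] <- mu[v] + sdv[v] * z
  }

  # AOD retrievals at two daily overpasses: one at each station plus random
  # points over the grid; missing-at-random mask mimics cloud gaps
  overpass <- c(10.5, 13.5) * 3600
  st_off <- stats::rnorm(config$n_stations, 0, 0.02)
  aod_parts <- vector("list", 2L)
  for (k in 1:2) {
    nr <- config$aod_per_day
    rl_lon <- stats::runif(n * nr, ext$lon[1], ext$lon[2])
    rl_lat <- stats::runif(n * nr, ext$lat[1], ext$lat[2])
    rnd <- data.frame(
      lon = rl_lon, lat = rl_lat,
      timestamp = as.POSIXct(rep(as.numeric(as.POSIXct(dates, tz = "UTC")),
                                 each = nr) + overpass[k],
                             origin = "1970-01-01", tz = "UTC"),
      aod = rep(aod_regional, each = nr) +
        aod_spatial_field(rl_lon, rl_lat, ext) +
        stats::rnorm(n * nr, 0, 0.03))
    stn <- data.frame(
      lon = rep(stations$lon, times = n),
      lat = rep(stations$lat, times = n),
      timestamp = as.POSIXct(rep(as.numeric(as.POSIXct(dates, tz = "UTC")),
                                 each = config$n_stations) + overpass[k],
                             origin = "1970-01-01", tz = "UTC"),
      aod = rep(aod_regional, each = config$n_stations) +
        rep(st_off, times = n))
    aod_parts[[k]] <- rbind(rnd, stn)
  }
  aod <- do.call(rbind, aod_parts)
  aod$aod <- pmax(aod$aod, 0.01)
  aod <- aod[stats::runif(nrow(aod)) >= config$aod_missing_prob, ,
             drop = FALSE]
  rownames(aod) <- NULL

  # hourly station PM2.5 generated from the calibration relationship at the
  # station's own AOD; hourly jitter vanishes with noise_sd = 0 so the
  # noise-free limit recovers the coefficients exactly
  rec_hours <- 8:16
  st_aod_day <- outer(st_off, aod_regional, "+")   # station x day
  pm_day <- cal$intercept + cal$aod_slope * st_aod_day +
    matrix(rep(cal$season * season_indicator(dates) +
                 cal$factor1 * f1 + cal$factor2 * f2, each = config$n_stations),
           nrow = config$n_stations) +
    matrix(stats::rnorm(config$n_stations * n, 0, cal$noise_sd),
           nrow = config$n_stations)
  jitter_sd <- min(cal$noise_sd, 0.3)
  nrec <- config$n_stations * n * length(rec_hours)
  pm25 <- data.frame(
    station_id = rep(stations$station_id, times = n * length(rec_hours)),
    lon = rep(stations$lon, times = n * length(rec_hours)),
    lat = rep(stations$lat, times = n * length(rec_hours)),
    timestamp = as.POSIXct(
      rep(rep(as.numeric(as.POSIXct(dates, tz = "UTC")),
              each = config$n_stations), times = length(rec_hours)) +
        rep(rec_hours * 3600, each = config$n_stations * n),
      origin = "1970-01-01", tz = "UTC"),
    pm25 = rep(as.vector(pm_day), times = length(rec_hours)) +
      stats::rnorm(nrec, 0, jitter_sd))

  env$aod <- aod
  env$pm25 <- pm25
  env$met <- met
  env$stations <- stations
  env
}

# Eq.-1 style inverse-time-weighted 15-day history of a daily series,
# evaluated for every day (NA for the first 15 days).
distributed_history <- function(x, L = 15) {
  n <- length(x)
  w <- 1 / seq_len(L)
  out <- rep(NA_real_, n)
  acc <- rep(0, n)
  for (l in seq_len(L)) {
    idx <- (l + 1):n
    acc[idx] <- acc[idx] + w[l] * x[idx - l]
  }
  if (n > L) out[(L + 1):n] <- acc[(L + 1):n] / sum(w)
  out
}

#' Generate the synthetic cohort with known ground truth
#'
#' Simulates per-subject-day AECOPD events from a Bernoulli hazard on the
#' logit scale: baseline log-odds (anchored so that `baseline_event_prob`
#' is the marginal per-person-day event rate), plus the configured
#' log-odds-ratio effects of one-day-lagged PM2.5 at the
#' residence, one-day-lagged ambient temperature, one-day-lagged dust
#' intensity and/or the 15-day distributed-lag dust statistic, plus a
#' Gaussian subject random intercept inducing within-subject clustering.
#' Every event day becomes a case roster row; subjects with no events
#' receive one clinic-visit control row on a date drawn uniformly from
#' eligible days. The first 16 days of the range are excluded as index days
#' so every row has a full look-back window.
#'
#' @param config A [synth_config()]; every odds ratio in `true_or` must be
#'   strictly positive.
#' @param env Environment from [generate_environment()] (either detail
#'   level) built from the same config.
#' @return List of class `dust_synth_cohort`:
#' \describe{
#'   \item{roster}{Data frame, one row per index date: `subject_id`, `lon`,
#'     `lat`, `age`, `asthma`, `smoking_active`, `fev1_fvc`, `index_date`,
#'     `event`, `n_events`, `in_catchment`.}
#'   \item{truth}{Ground truth: `dust_day_labels` (date, label),
#'     `linear_predictor` per roster row, per-day exposure vectors
#'     (`temp_c`, `intensity`, `dist15`, both in model units), the
#'     subject-by-day true and observed (satellite-masked) PM2.5 matrices,
#'     subject random intercepts, and the generating config.}
#' }
#' @export
generate_cohort <- function(config, env) {
  stopifnot(inherits(config, "synth_config"),
            inherits(env, "dust_synth_env"))
  or <- unlist(config$true_or)
  if (length(or) && any(or <= 0))
    stop_dl("all generating odds ratios must be strictly positive")
  known <- c("pm25", "temperature", "dust", "dust_distributed")
  if (length(setdiff(names(or), known)))
    stop_dl("unknown exposure(s) in true_or: ",
            paste(setdiff(names(or), known), collapse = ", "))
  set.seed(config$seed + 1L)

  daily <- env$daily
  n_days <- nrow(daily)
  n_sub <- config$n_subjects
  ext <- config$grid_extent
  cal <- config$true_calibration
  beta <- log(or)

  subj <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n_sub)),
    lon = stats::runif(n_sub, ext$lon[1], ext$lon[2]),
    lat = stats::runif(n_sub, ext$lat[1], ext$lat[2]),
    age = stats::rnorm(n_sub, 70, 8.7),
    asthma = stats::rbinom(n_sub, 1, config$asthma_prob),
    fev1_fvc = pmin(pmax(stats::rnorm(n_sub, 51.4, 13.4), 20), 90),
    smoking_baseline = stats::rbinom(n_sub, 1, config$smoking_prob),
    b = stats::rnorm(n_sub, 0, config$subject_sd))

  # true per-subject-day PM2.5 at the residence (calibration relationship
  # applied to a locally perturbed AOD field), and the satellite-masked
  # observable version
  aod_sub <- matrix(rep(daily$aod_regional, each = n_sub), nrow = n_sub) +
    aod_spatial_field(subj$lon, subj$lat, ext) +
    matrix(stats::rnorm(n_sub * n_days, 0, 0.03), nrow = n_sub)
  day_terms <- cal$season * daily$season + cal$factor1 * daily$f1 +
    cal$factor2 * daily$f2
  pm25_true <- cal$intercept + cal$aod_slope * aod_sub +
    matrix(rep(day_terms, each = n_sub), nrow = n_sub) +
    matrix(stats::rnorm(n_sub * n_days, 0, cal$noise_sd), nrow = n_sub)
  masked <- matrix(stats::runif(n_sub * n_days) < config$aod_missing_prob,
                   nrow = n_sub)
  pm25_obs <- pm25_true
  pm25_obs[masked] <- NA_real_

  intensity <- ifelse(daily$dust, daily$depol, 0) / config$intensity_scale
  dist15 <- distributed_history(intensity, 15)

  first_day <- 17L # full 15-day look-back plus the lag-1 day
  valid <- first_day:n_days
  eta <- matrix(0, nrow = n_sub, ncol = length(valid))
  add_effect <- function(eta, b1, x_mat) {
    eta + b1 * (x_mat - mean(x_mat, na.rm = TRUE))
  }
  if ("pm25" %in% names(beta))
    eta <- add_effect(eta, beta[["pm25"]], pm25_true[, valid - 1L])
  if ("temperature" %in% names(beta))
    eta <- add_effect(eta, beta[["temperature"]],
                      matrix(rep(daily$temp_c[valid - 1L], each = n_sub),
                             nrow = n_sub))
  if ("dust" %in% names(beta))
    eta <- add_effect(eta, beta[["dust"]],
                      matrix(rep(intensity[valid - 1L], each = n_sub),
                             nrow = n_sub))
  if ("dust_distributed" %in% names(beta))
    eta <- add_effect(eta, beta[["dust_distributed"]],
                      matrix(rep(dist15[valid], each = n_sub),
                             nrow = n_sub))
  eta <- eta + subj$b
  # anchor the intercept so baseline_event_prob is the marginal person-day
  # event rate (rare-event normalisation over effects and subject terms)
  alpha <- stats::qlogis(config$baseline_event_prob) -
    log(mean(exp(eta)))
  eta <- eta + alpha
  events <- matrix(stats::rbinom(length(eta), 1, stats::plogis(eta)),
                   nrow = n_sub)
  n_events <- rowSums(events)

  # event rows (one per subject-day event) plus one control clinic visit
  # per zero-event subject, assembled column-wise
  ev <- which(events == 1, arr.ind = TRUE)
  ev <- ev[order(ev[, 1], ev[, 2]), , drop = FALSE]
  zero <- which(n_events == 0)
  ctrl_col <- if (length(zero))
    sample(length(valid), length(zero), replace = TRUE) else integer()
  si <- c(ev[, 1], zero)
  ci <- c(ev[, 2], ctrl_col)
  is_case <- c(rep(TRUE, nrow(ev)), rep(FALSE, length(zero)))
  roster <- data.frame(
    subject_id = subj$subject_id[si], lon = subj$lon[si],
    lat = subj$lat[si], age = subj$age[si], asthma = subj$asthma[si],
    smoking_active = ifelse(is_case,
                            stats::rbinom(length(si), 1,
                                          config$smoking_prob),
                            subj$smoking_baseline[si]),
    fev1_fvc = subj$fev1_fvc[si],
    index_date = daily$date[valid[ci]],
    event = as.integer(is_case),
    n_events = n_events[si])
  lp <- eta[cbind(si, ci)]
  roster$in_catchment <- in_box(roster$lon, roster$lat, catchment_box())
  rownames(roster) <- NULL

  truth <- list(
    dust_day_labels = data.frame(
      date = daily$date,
      label = ifelse(daily$dust, daily$grade, "none")),
    linear_predictor = data.frame(
      subject_id = roster$subject_id, index_date = roster$index_date,
      eta = lp),
    dates = daily$date, subject_ids = subj$subject_id,
    temp_c = daily$temp_c, intensity = intensity, dist15 = dist15,
    pm25_true = pm25_true, pm25_obs = pm25_obs,
    subject_effects = subj$b, first_day = first_day, config = config)
  structure(list(roster = roster, truth = truth),
            class = "dust_synth_cohort")
}

#' Ground-truth exposure series for the synthetic cohort
#'
#' Builds the same per-subject, per-lag exposure table as
#' [build_exposure_series()], but from the generator's stored exposures
#' (observed PM2.5, i.e. with satellite gaps, and ambient temperature)
#' instead of interpolation -- the reference against which the kriging
#' stage is judged, and the input for parameter-recovery studies of the
#' risk stage.
#'
#' @param cohort A `dust_synth_cohort` from [generate_cohort()].
#' @param L_max Maximum lag (default 15).
#' @return Data frame with columns `subject_id`, `index_date`, `lag`,
#'   `date`, `pm25`, `pm25_source` (`"truth"` or `"missing"`),
#'   `temperature`.
#' @export
truth_exposure_series <- function(cohort, L_max = 15) {
  stopifnot(inherits(cohort, "dust_synth_cohort"))
  tr <- cohort$truth
  idx <- unique(cohort$roster[, c("subject_id", "index_date")])
  n_idx <- nrow(idx)
  lags <- 0:L_max
  out <- data.frame(
    subject_id = rep(idx$subject_id, each = length(lags)),
    index_date = rep(idx$index_date, each = length(lags)),
    lag = rep(lags, times = n_idx))
  out$date <- out$index_date - out$lag
  si <- match(out$subject_id, tr$subject_ids)
  di <- match(as.integer(out$date), as.integer(tr$dates))
  ok <- !is.na(di)
  out$pm25 <- NA_real_
  out$pm25[ok] <- tr$pm25_obs[cbind(si[ok], di[ok])]
  out$pm25_source <- ifelse(is.na(out$pm25), "missing", "truth")
  out$temperature <- NA_real_
  out$temperature[ok] <- tr$temp_c[di[ok]]
  out
}

#' Ground-truth dust-day table
#'
#' The daily dust series as the generator knows it (labels, not detected),
#' in the format [build_lag_table()] consumes.
#'
#' @param env A `dust_synth_env`.
#' @return Data frame with columns `date`, `depol`, `pm10`, `is_dust`,
#'   `grade`.
#' @export
truth_dust_days <- function(env) {
  stopifnot(inherits(env, "dust_synth_env"))
  with(env$daily, data.frame(date = date, depol = depol, pm10 = pm10,
                             is_dust = dust,
                             grade = ifelse(dust, grade, "none")))
}
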