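ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

test_that("collocation honors the space and time windows", {
  aod <- data.frame(lon = -80.200, lat = 25.700,
                    timestamp = ts_utc("2015-06-01 12:00:00"), aod = 0.3)
  stn <- data.frame(station_id = 1, lon = -80.210, lat = 25.710,
                    timestamp = ts_utc("2015-06-01 12:30:00"), pm25 = 12)
  pairs <- collocate(aod, stn)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$dist_deg, sqrt(2) * 0.010, tolerance = 1e-12)
  expect_equal(pairs$dt_hours, 0.5)
  expect_equal(pairs$season, 1L) # June

  # same site but 2 h apart: outside the temporal window
  stn2 <- stn; stn2$timestamp <- ts_utc("2015-06-01 14:00:00")
  stn2$lon <- aod$lon; stn2$lat <- aod$lat
  expect_equal(nrow(collocate(aod, stn2)), 0)
})

test_that("collocation ties break by time gap then station id", {
  aod <- data.frame(lon = -80.2, lat = 25.7,
                    timestamp = ts_utc("2015-06-01 12:00:00"), aod = 0.3)
  # two stations equidistant at 0.010 degrees, time gaps 0.4 h and 0.2 h:
  # enumerating candidates by hand, station 2 (smaller gap) must win
  stn <- data.frame(
    station_id = c(1, 2),
    lon = c(-80.21, -80.19), lat = c(25.7, 25.7),
    timestamp = ts_utc(c("2015-06-01 12:24:00", "2015-06-01 12:12:00")),
    pm25 = c(10, 20))
  pairs <- collocate(aod, stn)
  expect_equal(pairs$station_id, 2)
  expect_equal(pairs$pm25, 20)

  # identical distance and identical gap: lower station id wins
  stn$timestamp <- ts_utc(rep("2015-06-01 12:12:00", 2))
  expect_equal(collocate(aod, stn)$station_id, 1)
})

test_that("collocation output is invariant to input row order", {
  set.seed(11)
  n <- 60
  aod <- data.frame(lon = runif(n, -80.4, -80.0),
                    lat = runif(n, 25.5, 26.0),
                    timestamp = ts_utc("2015-06-01") + runif(n, 0, 86400),
                    aod = runif(n, 0.05, 0.4))
  stn <- data.frame(station_id = 1:8,
                    lon = runif(8, -80.4, -80.0),
                    lat = runif(8, 25.5, 26.0),
                    timestamp = ts_utc("2015-06-01") + runif(8, 0, 86400),
                    pm25 = runif(8, 5, 20))
  stn <- stn[rep(1:8, each = 24), ]
  stn$timestamp <- stn$timestamp + rep(0:23 * 3600, times = 8)
  a <- collocate(aod, stn, max_dist_deg = 0.2)
  b <- collocate(aod[sample(n), ], stn[sample(nrow(stn)), ],
                 max_dist_deg = 0.2)
  key <- function(p) p[order(p$timestamp, p$lon, p$lat), ]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})

test_that("negative AOD retrievals are dropped and bad rows are named", {
  stn <- data.frame(station_id = 1, lon = -80.2, lat = 25.7,
                    timestamp = ts_utc("2015-06-01 12:00:00"), pm25 = 10)
  aod <- data.frame(lon = -80.2, lat = 25.7,
                    timestamp = ts_utc("2015-06-01 12:00:00"),
                    aod = -0.05)
  expect_error(collocate(aod, stn), "non-negative")
  aod_bad <- data.frame(lon = c(-80.2, NA), lat = 25.7,
                        timestamp = ts_utc("2015-06-01 12:00:00"),
                        aod = 0.2)
  expect_error(collocate(aod_bad, stn), "rows: 2")
})

met_names <- c("wind_speed", "ceiling_height", "visibility",
               "dry_bulb_temp", "dew_point", "sea_level_pressure",
               "relative_humidity")

test_that("factor extraction matches a direct eigen-decomposition", {
  set.seed(21)
  X <- matrix(rnorm(4 * 7), nrow = 4)
  colnames(X) <- met_names
  fm <- fit_factors(as.data.frame(X))
  R <- cor(scale(X))
  e <- eigen(R, symmetric = TRUE)
  for (j in 1:2) {
    expected <- e$vectors[, j] * sqrt(e$values[j])
    got <- fm$loadings[, j]
    # sign convention may flip the whole column
    expect_true(max(abs(got - expected)) < 1e-10 ||
                  max(abs(got + expected)) < 1e-10)
  }
  expect_lte(sum(fm$variance_explained), 100)
  expect_true(all(diff(fm$variance_explained) <= 0))
})

test_that("a correlated temperature/dew-point block loads factor 1 alone", {
  set.seed(22)
  n <- 8000
  driver <- rnorm(n)
  met <- data.frame(
    wind_speed = rnorm(n), ceiling_height = rnorm(n),
    visibility = rnorm(n),
    dry_bulb_temp = driver + rnorm(n, 0, 0.1),
    dew_point = driver + rnorm(n, 0, 0.1),
    sea_level_pressure = rnorm(n), relative_humidity = rnorm(n))
  fm <- fit_factors(met)
  L <- abs(fm$loadings)
  expect_gt(L["dry_bulb_temp", 1], 0.9)
  expect_gt(L["dew_point", 1], 0.9)
  expect_true(all(L[c("wind_speed", "ceiling_height", "visibility",
                      "sea_level_pressure", "relative_humidity"), 1] < 0.06))
  # scores are standardized
  sc <- score_factors(fm, met)
  expect_equal(mean(sc$f1), 0, tolerance = 1e-8)
  expect_equal(sd(sc$f1), 1, tolerance = 1e-6)
})

test_that("constant meteorological columns are rejected by name", {
  met <- as.data.frame(matrix(rnorm(10 * 7), ncol = 7))
  names(met) <- met_names
  met$visibility <- 5
  expect_error(fit_factors(met), "visibility")
})

test_that("noise-free pairs recover the generating coefficients exactly", {
  set.seed(23)
  truth <- calibration_truth()
  pairs <- simulate_collocated_pairs(200, truth, noise_sd = 0)
  fit <- suppressWarnings(fit_calibration(pairs)) # perfect-fit notice
  expect_equal(unname(fit$coefficients),
               c(7.17, 21.44, 0.64, 1.85, -0.69), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("a 5-pair AOD-only fit equals the normal-equation solution", {
  pairs <- data.frame(aod = c(0.1, 0.2, 0.3, 0.4, 0.5),
                      pm25 = c(9, 12, 14, 18, 19))
  fit <- fit_calibration(pairs, terms = "aod", min_pairs = 5)
  X <- cbind(1, pairs$aod)
  beta <- solve(t(X) %*% X, t(X) %*% pairs$pm25)
  expect_equal(unname(fit$coefficients), drop(beta), tolerance = 1e-12)
})

test_that("OLS residuals are orthogonal to every design column", {
  set.seed(24)
  pairs <- simulate_collocated_pairs(300, noise_sd = 4)
  fit <- fit_calibration(pairs)
  X <- model.matrix(fit$fit)
  r <- residuals(fit$fit)
  expect_lt(max(abs(crossprod(X, r))) / nrow(X), 1e-10)
})

test_that("rank-deficient calibration designs fail listing the columns", {
  set.seed(25)
  pairs <- simulate_collocated_pairs(50, noise_sd = 1)
  pairs$f2 <- pairs$f1 # collinear
  expect_error(fit_calibration(pairs), "f2")
})

test_that("prediction applies the published coefficient arithmetic", {
  pairs <- simulate_collocated_pairs(100, noise_sd = 0)
  fit <- suppressWarnings(fit_calibration(pairs)) # perfect-fit notice
  expect_equal(as.numeric(predict_pm25(fit, aod = 1)), 7.17 + 21.44,
               tolerance = 1e-9)
  expect_equal(as.numeric(predict_pm25(fit, aod = 0)), 7.17,
               tolerance = 1e-9)
  # linearity: a 0.038 AOD contrast is worth 21.44 * 0.038
  d <- predict_pm25(fit, aod = 0.168) - predict_pm25(fit, aod = 0.130)
  expect_equal(as.numeric(d), 21.44 * 0.038, tolerance = 1e-9)
  # negative predictions flagged, not truncated
  expect_warning(p <- predict_pm25(fit, aod = -2), "negative")
  expect_lt(as.numeric(p), 0)
  expect_true(attr(p, "negative"))
  expect_error(predict_pm25(list(), aod = 1), "fitted")
})

test_that("factor scores join pairs at the nearest hour within the gap", {
  pairs <- data.frame(timestamp = ts_utc(c("2015-06-01 12:10:00",
                                           "2015-06-01 18:00:00")),
                      f1 = NA_real_, f2 = NA_real_)
  scores <- data.frame(timestamp = ts_utc(c("2015-06-01 12:00:00",
                                            "2015-06-01 13:00:00")),
                       f1 = c(0.5, 1.5), f2 = c(-1, 2))
  out <- attach_factor_scores(pairs, scores, max_gap_hours = 1.5)
  expect_equal(out$f1, c(0.5, NA)) # 12:10 -> 12:00; 18:00 beyond the gap
  expect_equal(out$f2, c(-1, NA))
})

test_that("cluster_logit accessors expose coefficients and covariance", {
  dat <- data.frame(x = c(rep(1, 25), rep(0, 35)),
                    outcome = c(rep(1, 20), rep(0, 5), rep(1, 10),
                                rep(0, 25)),
                    subject_id = 1:60)
  fit <- fit_logit_cluster(dat, outcome ~ x)
  expect_equal(coef(fit), fit$coef)
  expect_equal(vcov(fit), fit$robust_cov)
  expect_output(print(fit), "Cluster-robust")
})
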