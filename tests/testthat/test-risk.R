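# helper: one-row-per-subject data with a single binary covariate and the
# classic 2x2 layout (exposed cases, exposed controls, unexposed cases,
# unexposed controls)
make_2x2 <- function(a, b, c, d) {
  data.frame(
    outcome = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
    x = c(rep(1, a + b), rep(0, c + d)),
    subject_id = seq_len(a + b + c + d))
}

test_that("a single binary covariate reproduces the cross-product odds ratio", {
  dat <- make_2x2(20, 5, 10, 25)
  fit <- fit_logit_cluster(dat, outcome ~ x)
  expect_equal(unname(fit$or_[["x"]]), (20 * 25) / (10 * 5),
               tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$n_obs, 60)
  expect_equal(fit$n_clusters, 60)
})

test_that("coefficients agree with glm and the log-likelihood is monotone", {
  set.seed(51)
  n <- 400
  dat <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4),
                    subject_id = rep(1:80, each = 5))
  dat$outcome <- rbinom(n, 1, plogis(-1 + 0.8 * dat$x1 - 0.5 * dat$x2))
  fit <- fit_logit_cluster(dat, outcome ~ x1 + x2)
  ref <- glm(outcome ~ x1 + x2, family = binomial(), data = dat)
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-8)
  expect_true(all(diff(fit$loglik) >= -1e-9))
})

test_that("cluster covariance matches the sandwich package cross-check", {
  set.seed(52)
  n <- 300
  dat <- data.frame(x = rnorm(n), subject_id = rep(1:60, each = 5))
  b <- rnorm(60, 0, 0.7)
  dat$outcome <- rbinom(n, 1, plogis(-0.5 + 0.6 * dat$x +
                                       b[dat$subject_id]))
  fit <- fit_logit_cluster(dat, outcome ~ x)
  ref <- glm(outcome ~ x, family = binomial(), data = dat)
  V_ref <- sandwich::vcovCL(ref, cluster = dat$subject_id, type = "HC1",
                            cadjust = TRUE)
  expect_equal(unname(fit$robust_cov), unname(V_ref), tolerance = 1e-6)
})

test_that("with singleton clusters the covariance equals the HC form", {
  set.seed(53)
  n <- 200
  dat <- data.frame(x = rnorm(n), subject_id = seq_len(n))
  dat$outcome <- rbinom(n, 1, plogis(0.4 * dat$x))
  fit <- fit_logit_cluster(dat, outcome ~ x)
  # HC covariance with the same small-sample factor, computed from scratch
  X <- cbind(1, dat$x)
  p <- plogis(drop(X %*% fit$coef))
  bread <- solve(t(X * (p * (1 - p))) %*% X)
  meat <- crossprod(X * (dat$outcome - p))
  cfac <- (n / (n - 1)) * ((n - 1) / (n - 2))
  V_hc <- cfac * bread %*% meat %*% bread
  expect_equal(unname(fit$robust_cov), unname(V_hc), tolerance = 1e-12)
})

test_that("null covariates give near-unity odds ratios", {
  set.seed(54)
  ors <- replicate(20, {
    n <- 2000
    dat <- data.frame(x = rnorm(n), subject_id = seq_len(n))
    dat$outcome <- rbinom(n, 1, 0.3)
    fit_logit_cluster(dat, outcome ~ x)$or_[["x"]]
  })
  expect_true(all(ors > 0.85 & ors < 1.18))
})

test_that("fits are invariant to row order and cluster relabeling", {
  set.seed(55)
  n <- 240
  dat <- data.frame(x = rnorm(n), subject_id = rep(1:40, each = 6))
  dat$outcome <- rbinom(n, 1, plogis(0.5 * dat$x))
  fit <- fit_logit_cluster(dat, outcome ~ x)
  perm <- sample(n)
  fit2 <- fit_logit_cluster(dat[perm, ], outcome ~ x)
  expect_equal(fit$coef, fit2$coef, tolerance = 1e-10)
  expect_equal(fit$robust_cov, fit2$robust_cov, tolerance = 1e-10)
  dat3 <- dat
  dat3$subject_id <- paste0("Z", 41 - dat3$subject_id)
  fit3 <- fit_logit_cluster(dat3, outcome ~ x)
  expect_equal(fit$robust_cov, fit3$robust_cov, tolerance = 1e-10)
})

test_that("separation is detected and named", {
  dat <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                    outcome = c(rep(0, 20), rep(1, 20)),
                    subject_id = 1:40)
  expect_error(fit_logit_cluster(dat, outcome ~ x), "separation.*x")
})

test_that("frame assembly reproduces the catchment case/control margins", {
  roster <- make_margin_roster()
  frame_all <- assemble_frame(roster, min_events = 1)
  expect_equal(sum(frame_all$outcome == 1), 297)
  expect_equal(sum(frame_all$outcome == 0), 166)

  # subjects outside the box contribute nothing
  expect_false(any(frame_all$subject_id %in%
                     roster$subject_id[roster$lon < -81]))

  # min_events = 2 drops the 36 single-event case rows
  frame2 <- assemble_frame(roster, min_events = 2)
  expect_equal(sum(frame2$outcome == 1), 297 - 36)
  # min_events = 3 additionally drops the 34 two-event rows
  frame3 <- assemble_frame(roster, min_events = 3)
  expect_equal(sum(frame3$outcome == 1), 297 - 36 - 34)

  # filtering everything out fails loudly
  far <- roster
  far$lon <- -85
  expect_error(assemble_frame(far, min_events = 1), "empty")
})

test_that("model suite uses the prescribed covariate sets", {
  cfg <- synth_config(seed = 60)
  env <- generate_environment(cfg, detail = "daily")
  cohort <- generate_cohort(cfg, env)
  series <- truth_exposure_series(cohort)
  lags <- build_lag_table(cohort$roster, truth_dust_days(env))
  frame <- assemble_frame(cohort$roster, lags = lags, exposures = series,
                          min_events = 2)
  fits <- run_model_suite(frame)
  nm <- lapply(fits, function(f) names(f$coef))
  base <- c("(Intercept)", "age", "asthma", "smoking_active", "fev1_fvc")
  expect_equal(nm$m1, c(base, "pm25_lag1"))
  expect_equal(nm$m3, c(base, "dust1_intensity"))
  expect_equal(nm$m6, c(base, "pm25_lag1", "temp_lag1", "dust1_intensity"))
  # model 6 covariates are the union of models 4 and 3
  expect_setequal(nm$m6, union(nm$m4, nm$m3))
  # PM2.5 models are restricted to complete rows
  expect_equal(fits$m1$n_obs, sum(frame$complete))
  expect_equal(fits$m2$n_obs, nrow(frame))
  expect_lt(fits$m6$n_obs, fits$m5$n_obs)
})

test_that("the lag sweep reports inestimable cells as NA", {
  cfg <- synth_config(seed = 61, true_or = c(dust = 3))
  env <- generate_environment(cfg, detail = "daily")
  cohort <- generate_cohort(cfg, env)
  series <- truth_exposure_series(cohort)
  lags <- build_lag_table(cohort$roster, truth_dust_days(env))
  frame <- assemble_frame(cohort$roster, lags = lags, exposures = series,
                          min_events = 2)
  # constant exposure at one lag: overwrite lag-5 intensity with a constant
  lags_const <- lags
  lags_const$x_intensity[lags_const$lag == 5] <- 0.2
  sw <- lag_sweep(frame, lags_const, lags = c(1, 5), kind = "intensity")
  expect_false(is.na(sw$or[sw$lag == 1]))
  expect_true(is.na(sw$or[sw$lag == 5]))
  expect_match(sw$note[sw$lag == 5], "collinear|constant")
})

test_that("an effect planted at lag 1 decays across the lag sweep", {
  cfg <- synth_config(seed = 62, true_or = c(dust = 6),
                      baseline_event_prob = 1e-3)
  env <- generate_environment(cfg, detail = "daily")
  cohort <- generate_cohort(cfg, env)
  series <- truth_exposure_series(cohort)
  lags <- build_lag_table(cohort$roster, truth_dust_days(env))
  frame <- assemble_frame(cohort$roster, lags = lags, exposures = series,
                          min_events = 2)
  sw <- lag_sweep(frame, lags, lags = c(1, 10), kind = "intensity")
  expect_gt(sw$or[sw$lag == 1], sw$or[sw$lag == 10])
  expect_gt(sw$or[sw$lag == 1], 2)
})
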