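# Time-lagged dust exposure variables: binary event, same-lag intensity, and
# the distributive inverse-time-weighted cumulative intensity.

#' Distributive inverse-time-weighted lagged exposure
#'
#' Collapses a daily dust-intensity series over the `L` days preceding an
#' index day into a single scalar, weighting the intensity on lag day `l` by
#' `1/l` and normalising so the weights sum to one:
#' \deqn{X_L = \frac{\sum_{l=1}^{L} D_l / l}{\sum_{l=1}^{L} 1/l}.}
#' Recent days therefore dominate, but every day in the look-back window
#' contributes. The statistic always lies between `min(D)` and `max(D)`.
#'
#' @param D Numeric vector of dust intensities (volume depolarization ratio;
#'   0 on non-dust days), where `D[l]` is the intensity `l` days before the
#'   index day. Must have length at least `L`.
#' @param L Integer look-back length in days, between 1 and 15.
#' @return A single numeric value in intensity units, or `NA` (with attribute
#'   `"missing_lags"`) when any contributing lag is `NA`.
#' @examples
#' distributed_lag(c(1, 0), 2)        # (1 + 0/2) / (1 + 1/2) = 2/3
#' distributed_lag(rep(0.2, 15), 15)  # constant series -> 0.2
#' @export
distributed_lag <- function(D, L) {
  if (length(L) != 1L || is.na(L) || L < 1L || L > 15L || L != round(L))
    stop_dl("L must be a single integer between 1 and 15")
  L <- as.integer(L)
  if (length(D) < L)
    stop_dl(sprintf("intensity series has length %d but L = %d", length(D), L))
  d <- D[seq_len(L)]
  if (anyNA(d)) {
    out <- NA_real_
    attr(out, "missing_lags") <- which(is.na(d))
    return(out)
  }
  w <- 1 / seq_len(L)
  sum(d * w) / sum(w)
}

#' Build the per-subject lagged dust exposure table
#'
#' For each subject index date (exacerbation date for cases, clinic-visit
#' date for controls) and each lag 0..`L_max`, constructs the three dust
#' exposure variables: `x_binary` (1 when the lagged calendar day is a dust
#' day), `x_intensity` (that day's depolarization ratio, 0 on non-dust days)
#' and `x_distributed` (the [distributed_lag()] statistic over lags `1..L`;
#' lag 0 is defined as the same-day intensity, matching the convention under
#' which the lag-0 intensity and distributed-lag estimates coincide).
#'
#' @param index_dates Data frame with columns `subject_id` and `index_date`
#'   (one row per subject index date), or an exposure-series data frame from
#'   [build_exposure_series()] from which the unique pairs are taken.
#' @param dust_days Data frame with columns `date`, `is_dust` and `depol`
#'   (daily depolarization ratio), e.g. from [detect_dust_days()] or
#'   [truth_dust_days()]. Days absent from the table are treated as outside
#'   the data record: their lag variables are `NA`.
#' @param L_max Maximum lag in days (default 15).
#' @return Data frame with columns `subject_id`, `index_date`, `lag`,
#'   `x_binary`, `x_intensity`, `x_distributed`.
#' @export
build_lag_table <- function(index_dates, dust_days, L_max = 15) {
  assert_columns(index_dates, c("subject_id", "index_date"), "index_dates")
  assert_columns(dust_days, c("date", "is_dust", "depol"), "dust_days")
  idx <- unique(index_dates[, c("subject_id", "index_date")])
  idx$index_date <- as_date_strict(idx$index_date, "index_date")
  dd <- dust_days
  dd$date <- as_date_strict(dd$date, "dust_days$date")
  if (anyDuplicated(dd$date))
    stop_dl("dust_days contains duplicated dates")
  # daily intensity: depol on dust days, 0 otherwise (non-dust days carry
  # zero dust, not missing); days outside the record are NA
  dd_int <- as.integer(dd$date)
  daily_intensity <- ifelse(dd$is_dust, dd$depol, 0)
  intensity_on <- function(date_int) {
    pos <- match(date_int, dd_int)
    daily_intensity[pos]
  }
  n_idx <- nrow(idx)
  lags <- 0:L_max
  out <- data.frame(
    subject_id = rep(idx$subject_id, each = length(lags)),
    index_date = rep(idx$index_date, each = length(lags)),
    lag = rep(lags, times = n_idx)
  )
  idx_int <- as.integer(idx$index_date)
  lag_date_int <- rep(idx_int, each = length(lags)) - out$lag
  pos <- match(lag_date_int, dd_int)
  known <- !is.na(pos)
  out$x_binary <- ifelse(known, as.integer(dd$is_dust[pos]), NA_integer_)
  out$x_intensity <- intensity_on(lag_date_int)

  # distributed statistic per index date: cumulative over lags 1..L, with
  # the lag-0 row defined as the same-day intensity; D is the n_idx x L_max
  # matrix of intensities on the 1..L_max days before each index date
  D <- matrix(intensity_on(rep(idx_int, times = L_max) -
                             rep(seq_len(L_max), each = n_idx)),
              nrow = n_idx)
  w <- 1 / seq_len(L_max)
  xd <- matrix(NA_real_, nrow = n_idx, ncol = L_max + 1L)
  xd[, 1L] <- out$x_intensity[out$lag == 0L]
  num <- rep(0, n_idx)
  for (L in seq_len(L_max)) {
    num <- num + w[L] * D[, L]
    xd[, L + 1L] <- num / sum(w[seq_len(L)])
  }
  out$x_distributed <- as.vector(t(xd))
  out
}
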