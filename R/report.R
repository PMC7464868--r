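# Stratified environmental summaries and the contrast arithmetic used in
# reporting (percent increases, mean differences, Welch contrasts).

#' Stratified means of environmental variables
#'
#' Cell means with 95% confidence intervals by region (inside/outside the
#' catchment box, plus the pooled region) and dust-intensity stratum
#' (`none`, `low`, `medium`, `high`, from the daily dust grades). Intervals
#' use the normal approximation, switching to Student-t below 30
#' observations. Empty cells are omitted with a message; single-observation
#' cells are flagged `degenerate`.
#'
#' @param records Data frame of daily field records with columns `lon`,
#'   `lat`, `date` and one or more of the summary variables (any numeric
#'   columns beyond the coordinates/date are summarised).
#' @param dust_days A `dust_days` data frame giving the daily `grade`.
#' @param catchment Bounding box (see [catchment_box()]).
#' @return Data frame with columns `region` (`catchment`, `outside`, `all`),
#'   `stratum`, `variable`, `mean`, `ci_lo`, `ci_hi`, `n`, `degenerate`.
#' @export
stratified_means <- function(records, dust_days,
                             catchment = catchment_box()) {
  assert_columns(records, c("lon", "lat", "date"), "records")
  assert_columns(dust_days, c("date", "grade"), "dust_days")
  vars <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                  c("lon", "lat"))
  if (!length(vars)) stop_dl("records contain no summary variables")
  rec <- records
  rec$date <- as_date_strict(rec$date)
  grade <- dust_days$grade[match(rec$date, as.Date(dust_days$date))]
  rec$stratum <- ifelse(is.na(grade), "none", grade)
  rec$region <- ifelse(in_box(rec$lon, rec$lat, catchment),
                       "catchment", "outside")
  out <- list()
  for (region in c("catchment", "outside", "all")) {
    sub <- if (region == "all") rec else rec[rec$region == region, ]
    for (stratum in c("none", "low", "medium", "high")) {
      cell <- sub[sub$stratum == stratum, , drop = FALSE]
      for (v in vars) {
        x <- cell[[v]]
        x <- x[!is.na(x)]
        if (!length(x)) {
          message(sprintf("empty cell: %s / %s / %s", region, stratum, v))
          next
        }
        n <- length(x); m <- mean(x)
        se <- if (n > 1) stats::sd(x) / sqrt(n) else 0
        q <- if (n >= 30) 1.96 else stats::qt(0.975, df = max(n - 1, 1))
        out[[length(out) + 1L]] <- data.frame(
          region = region, stratum = stratum, variable = v, mean = m,
          ci_lo = m - q * se, ci_hi = m + q * se, n = n,
          degenerate = n < 2)
      }
    }
  }
  do.call(rbind, out)
}

#' Percent increase of one mean over a reference mean
#'
#' `100 * (mean_event / mean_reference - 1)`; display convention is one
#' decimal place (applied by the caller, not here, so that the reciprocal
#' identity `(1 + p12/100)(1 + p21/100) = 1` holds exactly).
#'
#' @param mean_event Mean during the condition of interest.
#' @param mean_reference Reference mean; must be strictly positive.
#' @return Percent increase (can be negative).
#' @examples
#' percent_increase(0.179, 0.130) # ~37.7
#' @export
percent_increase <- function(mean_event, mean_reference) {
  if (any(mean_reference <= 0))
    stop_dl("reference mean must be strictly positive")
  100 * (mean_event / mean_reference - 1)
}

#' Difference of two means
#'
#' Companion to [percent_increase()] for contrasts quoted as absolute
#' differences (e.g. AOD differences between strata).
#'
#' @param mean_event,mean_reference The two means.
#' @return `mean_event - mean_reference`.
#' @export
mean_difference <- function(mean_event, mean_reference) {
  mean_event - mean_reference
}

#' Welch two-sample contrast from summary statistics
#'
#' Difference of means with an unequal-variance (Welch-Satterthwaite)
#' confidence interval and two-sided p-value. Operates on summary
#' statistics so that contrasts can be formed from published or aggregated
#' cells; [welch_contrast_samples()] wraps it for raw samples.
#'
#' @param mean_a,sd_a,n_a Summary statistics of sample A.
#' @param mean_b,sd_b,n_b Summary statistics of sample B.
#' @return List: `difference`, `ci95` (length 2), `t`, `df`, `p`,
#'   `degenerate` (TRUE when both variances are zero, in which case the
#'   p-value is 1 for a zero difference and 0 otherwise).
#' @export
welch_contrast <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop_dl("need at least 2 observations per side")
  diff <- mean_a - mean_b
  va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
  if (va + vb == 0) {
    return(list(difference = diff, ci95 = c(diff, diff), t = NA_real_,
                df = NA_real_, p = if (diff == 0) 1 else 0,
                degenerate = TRUE))
  }
  se <- sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  tstat <- diff / se
  q <- stats::qt(0.975, df)
  list(difference = diff, ci95 = c(diff - q * se, diff + q * se),
       t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df),
       degenerate = FALSE)
}

#' Welch contrast from raw samples
#'
#' @param x,y Numeric vectors.
#' @return See [welch_contrast()].
#' @export
welch_contrast_samples <- function(x, y) {
  welch_contrast(mean(x), stats::sd(x), length(x),
                 mean(y), stats::sd(y), length(y))
}
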