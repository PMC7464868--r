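# Dust-day identification and intensity grading from LIDAR volume
# depolarization ratio, corroborated by in situ PM10.

#' Grade dust intensity from the depolarization ratio
#'
#' Mineral dust is non-spherical and depolarizes LIDAR backscatter; the daily
#' volume depolarization ratio therefore proxies dust intensity. Grades:
#' `low` for ratios at or below 0.10, `medium` strictly between 0.10 and
#' 0.15, `high` at or above 0.15. The boundary values are assigned to the
#' outer grades (half-open intervals), so the grade is a monotone step
#' function of the ratio.
#'
#' @param depol Numeric vector of volume depolarization ratios in \[0, 1\].
#' @return Character vector with values `"low"`, `"medium"`, `"high"`.
#' @examples
#' grade_intensity(c(0.05, 0.13, 0.16))
#' @export
grade_intensity <- function(depol) {
  if (!is.numeric(depol) || anyNA(depol) ||
      any(depol < 0) || any(depol > 1))
    stop_dl("depol must be numeric in [0, 1] with no missing values")
  ifelse(depol <= 0.10, "low", ifelse(depol < 0.15, "medium", "high"))
}

#' Detect dust days from daily depolarization and PM10
#'
#' A day is flagged as a dust day when the depolarization ratio reaches
#' `depol_threshold` *and* the daily PM10 corroborates: it must exceed
#' `pm10_quantile` times the 30-day running median of PM10. The multiplier
#' sits below one so that the PM10 gate vetoes depolarization artifacts on
#' genuinely clean-air days without failing inside long dust episodes,
#' where the rolling median itself is dust-inflated. Intensity grades
#' ([grade_intensity()]) are assigned on dust days only.
#'
#' @param daily_depol Data frame with columns `date`, `depol`.
#' @param daily_pm10 Data frame with columns `date`, `pm10` covering exactly
#'   the same dates.
#' @param depol_threshold Minimum depolarization ratio for a dust day
#'   (default 0.08, below the 0.10 mild-grade boundary so that mild events
#'   are still detected).
#' @param pm10_quantile Multiplier applied to the 30-day rolling median of
#'   PM10 to form the corroboration threshold (default 0.75).
#' @param baseline_days Width of the rolling median window (default 30).
#' @return Data frame of class `dust_days` with columns `date`, `depol`,
#'   `pm10`, `is_dust`, `grade` (`"none"` on non-dust days).
#' @export
detect_dust_days <- function(daily_depol, daily_pm10,
                             depol_threshold = 0.08,
                             pm10_quantile = 0.75,
                             baseline_days = 30) {
  assert_columns(daily_depol, c("date", "depol"), "daily_depol")
  assert_columns(daily_pm10, c("date", "pm10"), "daily_pm10")
  if (depol_threshold <= 0 || depol_threshold >= 1)
    stop_dl("depol_threshold must be in (0, 1)")
  if (pm10_quantile <= 0 || pm10_quantile > 1)
    stop_dl("pm10_quantile must be in (0, 1]")
  a <- daily_depol; a$date <- as_date_strict(a$date)
  b <- daily_pm10;  b$date <- as_date_strict(b$date)
  a <- a[order(a$date), ]; b <- b[order(b$date), ]
  if (nrow(a) != nrow(b) || any(a$date != b$date)) {
    off <- union(setdiff(as.character(a$date), as.character(b$date)),
                 setdiff(as.character(b$date), as.character(a$date)))
    if (!length(off)) off <- "duplicated dates"
    stop_dl("depol and pm10 series are misaligned on dates: ",
            paste(utils::head(off, 10), collapse = ", "))
  }
  if (any(a$depol < 0 | a$depol > 1, na.rm = TRUE))
    stop_dl("depol must lie in [0, 1]")
  k <- min(baseline_days + 1 - baseline_days %% 2, # odd window width
           nrow(a) - (1 - nrow(a) %% 2))
  baseline <- if (k >= 3) {
    as.numeric(stats::runmed(b$pm10, k, endrule = "median"))
  } else rep(stats::median(b$pm10), nrow(b))
  is_dust <- !is.na(a$depol) & a$depol >= depol_threshold &
    !is.na(b$pm10) & b$pm10 > baseline * pm10_quantile
  grade <- rep("none", nrow(a))
  grade[is_dust] <- grade_intensity(a$depol[is_dust])
  out <- data.frame(date = a$date, depol = a$depol, pm10 = b$pm10,
                    is_dust = is_dust, grade = grade)
  class(out) <- c("dust_days", class(out))
  out
}

#' Monthly summary of dust-event depolarization
#'
#' Per year and month, the mean depolarization ratio over dust days only,
#' a normal-approximation 95% confidence interval, and the dust-day count;
#' yearly totals are appended as rows with `month = NA`. Months with no dust
#' days are omitted. Cells with a single dust day carry a degenerate
#' (zero-width) interval flagged via the `degenerate` column.
#'
#' @param dust_days A `dust_days` data frame from [detect_dust_days()].
#' @return Data frame with columns `year`, `month`, `mean_depol`, `ci_lo`,
#'   `ci_hi`, `n_days`, `degenerate`.
#' @export
dust_summary_by_month <- function(dust_days) {
  assert_columns(dust_days, c("date", "depol", "is_dust"), "dust_days")
  dd <- dust_days[dust_days$is_dust, , drop = FALSE]
  if (!nrow(dd)) stop_dl("no dust days to summarise")
  yr <- as.integer(format(dd$date, "%Y"))
  mo <- as.integer(format(dd$date, "%m"))
  cell <- function(x, year, month) {
    n <- length(x); m <- mean(x)
    se <- if (n > 1) stats::sd(x) / sqrt(n) else 0
    data.frame(year = year, month = month, mean_depol = m,
               ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se,
               n_days = n, degenerate = n < 2)
  }
  parts <- list()
  for (y in sort(unique(yr))) {
    for (m in sort(unique(mo[yr == y]))) {
      parts[[length(parts) + 1L]] <- cell(dd$depol[yr == y & mo == m], y, m)
    }
    parts[[length(parts) + 1L]] <- cell(dd$depol[yr == y], y, NA_integer_)
  }
  do.call(rbind, parts)
}
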