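# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dl <- function(...) stop(..., call. = FALSE)

assert_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_dl(sprintf("%s is missing required column(s): %s",
                    what, paste(miss, collapse = ", ")))
  invisible(df)
}

as_date_strict <- function(x, what = "date") {
  d <- tryCatch(as.Date(x), error = function(e) NULL)
  if (is.null(d) || anyNA(d))
    stop_dl(sprintf("could not parse %s values as dates", what))
  d
}

# Euclidean distance in degrees; adequate at the sub-0.1 degree scales used
# for collocation and local interpolation (no great-circle correction).
dist_deg <- function(lon1, lat1, lon2, lat2) {
  sqrt((lon1 - lon2)^2 + (lat1 - lat2)^2)
}

# Season indicator: 0 = October-March, 1 = April-September.
season_indicator <- function(dates) {
  m <- as.integer(format(as.Date(dates), "%m"))
  as.integer(m >= 4L & m <= 9L)
}

in_box <- function(lon, lat, box) {
  lon >= box$lon[1] & lon <= box$lon[2] & lat >= box$lat[1] & lat <= box$lat[2]
}

#' Miami catchment bounding box
#'
#' The longitude/latitude box (81-80 degrees W, 25-27.15 degrees N) used to
#' restrict subjects to the study catchment area.
#'
#' @return A list with elements `lon` and `lat`, each a length-2 numeric range.
#' @export
catchment_box <- function() {
  list(lon = c(-81, -80), lat = c(25, 27.15))
}
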