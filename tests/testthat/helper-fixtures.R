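# Fixtures built in code: a deterministic roster reproducing the published
# catchment marginals, and small spatial fields for interpolation tests.

# Roster with the study's catchment margins: 194 controls (28 outside the
# catchment), 42 one-event subjects (6 outside), 19 two-event subjects
# (2 outside), 41 subjects with >= 3 events (2 outside, 3 events each;
# inside subjects carry 227 events). Inside the catchment this yields 297
# case rows and 166 control rows.
make_margin_roster <- function() {
  inside <- c(lon = -80.5, lat = 26)
  outside <- c(lon = -82, lat = 26)
  base_date <- as.Date("2015-06-01")
  rows <- list()
  sid <- 0
  add_subject <- function(n_events, loc) {
    sid <<- sid + 1
    n_rows <- max(n_events, 1)
    data.frame(
      subject_id = sprintf("T%03d", sid),
      lon = loc[["lon"]], lat = loc[["lat"]],
      age = 70, asthma = 0, smoking_active = 0, fev1_fvc = 50,
      index_date = base_date + seq_len(n_rows) + 20 * sid,
      event = if (n_events == 0) 0L else 1L,
      n_events = n_events)
  }
  for (i in 1:166) rows[[length(rows) + 1]] <- add_subject(0, inside)
  for (i in 1:28) rows[[length(rows) + 1]] <- add_subject(0, outside)
  for (i in 1:36) rows[[length(rows) + 1]] <- add_subject(1, inside)
  for (i in 1:6) rows[[length(rows) + 1]] <- add_subject(1, outside)
  for (i in 1:17) rows[[length(rows) + 1]] <- add_subject(2, inside)
  for (i in 1:2) rows[[length(rows) + 1]] <- add_subject(2, outside)
  # 39 inside subjects totalling 227 events: 32 with 6 events, 7 with 5
  for (i in 1:32) rows[[length(rows) + 1]] <- add_subject(6, inside)
  for (i in 1:7) rows[[length(rows) + 1]] <- add_subject(5, inside)
  for (i in 1:2) rows[[length(rows) + 1]] <- add_subject(3, outside)
  do.call(rbind, rows)
}

# smooth deterministic space-time field for interpolation accuracy checks
smooth_field <- function(lon, lat, day_num) {
  10 + 3 * sin(2 * pi * lon / 0.8) + 2 * cos(2 * pi * lat / 0.8) +
    0.5 * day_num
}

# independent inverse-distance oracle (power 2, combined metric)
idw_oracle <- function(pts, target, anisotropy) {
  d <- sqrt((pts$lon - target$lon)^2 + (pts$lat - target$lat)^2 +
              (anisotropy * (as.numeric(as.Date(pts$day)) -
                               as.numeric(as.Date(target$day))))^2)
  if (any(d < 1e-12)) return(mean(pts$value[d < 1e-12]))
  w <- 1 / d^2
  sum(w * pts$value) / sum(w)
}

# brute-force evaluation of the inverse-time-weighted statistic, written
# as a plain loop so it stays independent of the package implementation
brute_distributed <- function(D, L) {
  num <- 0
  den <- 0
  for (l in 1:L) {
    num <- num + D[l] * (1 / l)
    den <- den + 1 / l
  }
  num / den
}
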