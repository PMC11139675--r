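# Sunrise/sunset computation (NOAA solar-position formulation) and the
# signed sun-anchored offset statistic used for activity-timing analysis.

.deg2rad <- function(d) d * pi / 180
.rad2deg <- function(r) r * 180 / pi

# NOAA spreadsheet algorithm: sunrise/sunset as minutes after 00:00 UTC for
# the given civil date, zenith 90.833 deg (refraction + solar radius).
.noaa_sun_utc_minutes <- function(date, lat, lon) {
  date <- as.Date(date)
  jd <- as.numeric(date) + 2440587.5 + 0.5  # Julian day at 12:00 UTC
  jc <- (jd - 2451545) / 36525
  L0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  M <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  C <- sin(.deg2rad(M)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(.deg2rad(2 * M)) * (0.019993 - 0.000101 * jc) +
    sin(.deg2rad(3 * M)) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * jc
  lambda <- true_long - 0.00569 - 0.00478 * sin(.deg2rad(omega))
  eps0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - 0.001813 * jc))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(.deg2rad(omega))
  decl <- asin(sin(.deg2rad(eps)) * sin(.deg2rad(lambda)))
  yv <- tan(.deg2rad(eps / 2))^2
  eot <- 4 * .rad2deg(
    yv * sin(2 * .deg2rad(L0)) - 2 * e * sin(.deg2rad(M)) +
      4 * e * yv * sin(.deg2rad(M)) * cos(2 * .deg2rad(L0)) -
      0.5 * yv^2 * sin(4 * .deg2rad(L0)) - 1.25 * e^2 * sin(2 * .deg2rad(M)))
  phi <- .deg2rad(lat)
  cosha <- (cos(.deg2rad(90.833)) - sin(phi) * sin(decl)) / (cos(phi) * cos(decl))
  if (any(cosha < -1 | cosha > 1)) {
    stop("sun never rises/sets at this latitude and date; supply a lookup table")
  }
  ha <- .rad2deg(acos(cosha))
  noon <- 720 - 4 * lon - eot
  list(sunrise = noon - 4 * ha, sunset = noon + 4 * ha)
}

#' Sunrise and sunset for a date and site
#'
#' Computes local sunrise/sunset instants from the NOAA solar-position
#' algorithm (zenith 90.833 deg), or takes them from an injected lookup
#' table. Valid away from polar latitudes.
#'
#' @param date Date (scalar).
#' @param lat,lon Site coordinates in decimal degrees (lon east-positive).
#' @param tz Civil time zone for the returned instants.
#' @param lookup Optional data.frame with columns `date`, `sunrise_local`,
#'   `sunset_local` (`"HH:MM"` or `"HH:MM:SS"` strings); overrides
#'   computation for matching dates.
#' @return A list of class `solar_day`: `date`, `sunrise_local`,
#'   `sunset_local` (POSIXct in `tz`), `daylight_h`.
#' @export
sun_times <- function(date, lat, lon, tz = "Europe/Dublin", lookup = NULL) {
  date <- as.Date(date)
  stopifnot(abs(lat) < 66)
  if (!is.null(lookup)) {
    row <- lookup[as.Date(lookup$date) == date, , drop = FALSE]
    if (nrow(row) == 1) {
      sr <- as.POSIXct(paste(date, row$sunrise_local), tz = tz)
      ss <- as.POSIXct(paste(date, row$sunset_local), tz = tz)
      return(structure(list(date = date, sunrise_local = sr, sunset_local = ss,
                            daylight_h = as.numeric(difftime(ss, sr, units = "hours"))),
                       class = "solar_day"))
    }
  }
  mins <- .noaa_sun_utc_minutes(date, lat, lon)
  midnight_utc <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  sr <- to_local_time(midnight_utc + mins$sunrise * 60, tz)
  ss <- to_local_time(midnight_utc + mins$sunset * 60, tz)
  structure(list(date = date, sunrise_local = sr, sunset_local = ss,
                 daylight_h = as.numeric(difftime(ss, sr, units = "hours"))),
            class = "solar_day")
}

#' @export
print.solar_day <- function(x, ...) {
  cat(sprintf("%s: sunrise %s, sunset %s (%.2f h daylight)\n",
              format(x$date), format(x$sunrise_local, "%H:%M"),
              format(x$sunset_local, "%H:%M"), x$daylight_h))
  invisible(x)
}

#' Signed sunrise/sunset offset of an event
#'
#' Events between 00:00 and 11:59 local are referenced to sunrise, events
#' between 12:00 and 23:59 to sunset. The offset magnitude is the absolute
#' time difference to the reference in hours; the sign is positive when the
#' event falls in daylight (between sunrise and sunset inclusive) and
#' negative in darkness. Offsets at sunrise/sunset are exactly zero.
#'
#' @param t_local POSIXct event time (civil local time, same date as `solar`).
#' @param solar A `solar_day` from [sun_times()].
#' @return A list: `reference_event` ("sunrise"/"sunset"), `offset_h`
#'   (signed hours), `is_daylight`.
#' @export
offset_event <- function(t_local, solar) {
  lt <- as.POSIXlt(t_local)
  before_noon <- lt$hour < 12
  ref_name <- if (before_noon) "sunrise" else "sunset"
  ref <- if (before_noon) solar$sunrise_local else solar$sunset_local
  mag <- abs(as.numeric(difftime(t_local, ref, units = "hours")))
  daylight <- t_local >= solar$sunrise_local & t_local <= solar$sunset_local
  list(reference_event = ref_name,
       offset_h = if (daylight) mag else -mag,
       is_daylight = daylight)
}

#' Sun-anchored offsets for a table of events
#'
#' Vectorised wrapper around [sun_times()] + [offset_event()]: computes one
#' solar day per distinct event date (or via `lookup`) and the signed offset
#' for every event.
#'
#' @param events data.frame with `t_local` (POSIXct) and `date` columns
#'   (as produced by [detect_interactions()]).
#' @param lat,lon Site coordinates (degrees).
#' @param tz Civil time zone.
#' @param lookup Optional sunrise/sunset lookup table (see [sun_times()]).
#' @return `events` with added columns `reference_event`, `offset_h`,
#'   `is_daylight`.
#' @export
event_offsets <- function(events, lat, lon, tz = "Europe/Dublin", lookup = NULL) {
  if (!nrow(events)) {
    events$reference_event <- character(0)
    events$offset_h <- numeric(0)
    events$is_daylight <- logical(0)
    return(events)
  }
  days <- lapply(setNames(nm = as.character(unique(events$date))), function(d) {
    sun_times(as.Date(d), lat, lon, tz = tz, lookup = lookup)
  })
  res <- lapply(seq_len(nrow(events)), function(i) {
    offset_event(events$t_local[i], days[[as.character(events$date[i])]])
  })
  events$reference_event <- vapply(res, `[[`, "", "reference_event")
  events$offset_h <- vapply(res, `[[`, 0, "offset_h")
  events$is_daylight <- vapply(res, `[[`, TRUE, "is_daylight")
  events
}

#' Compare sun-anchored offsets across seasons
#'
#' Kruskal-Wallis test on signed offsets grouped by season, with Dunn
#' pairwise post-hoc comparisons under Benjamini-Hochberg adjustment and
#' per-season descriptive summaries. Seasons with fewer than two
#' observations are excluded with a warning.
#'
#' @param offset_h Numeric vector of signed offsets (hours).
#' @param season Character vector of season labels, same length.
#' @return A list: `kw` (a `rank_test` result), `dunn` (pairwise table),
#'   `summary` (per-season n, mean, median, IQR).
#' @export
seasonal_offset_comparison <- function(offset_h, season) {
  groups <- split(offset_h, season)
  small <- vapply(groups, length, 0L) < 2
  if (any(small)) {
    warning("excluding season(s) with < 2 observations: ",
            paste(names(groups)[small], collapse = ", "))
    groups <- groups[!small]
  }
  if (length(groups) < 2) stop("need at least 2 non-empty season groups")
  summ <- do.call(rbind, c(lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(season = g, n = length(v), mean = mean(v), median = median(v),
               iqr = IQR(v), stringsAsFactors = FALSE)
  }), make.row.names = FALSE))
  list(kw = kruskal_wallis(groups), dunn = dunn_posthoc(groups), summary = summ)
}

#' Local-time histogram of events
#'
#' Shares of events per local clock-time bin (bins anchored at midnight,
#' right-open, width `bin_h` hours). Optionally stratified by a grouping
#' factor (e.g. season or habitat class); shares then sum to 100 within each
#' group.
#'
#' @param t_local POSIXct event times (civil local).
#' @param bin_h Bin width in hours; must divide 24.
#' @param by Optional grouping vector.
#' @return data.frame with `bin` (label `"HH:00-HH:59"`), `start_h`, `n`,
#'   `pct`, and `group` when `by` is given.
#' @export
clock_histogram <- function(t_local, bin_h = 3, by = NULL) {
  if (24 %% bin_h != 0) stop("bin_h must divide 24")
  starts <- seq(0, 24 - bin_h, by = bin_h)
  labels <- sprintf("%02d:00-%02d:59", starts, starts + bin_h - 1)
  one <- function(tl) {
    lt <- as.POSIXlt(tl)
    hfrac <- lt$hour + lt$min / 60 + lt$sec / 3600
    idx <- factor(floor(hfrac / bin_h), levels = seq_along(starts) - 1)
    n <- as.integer(table(idx))
    data.frame(bin = labels, start_h = starts, n = n,
               pct = if (sum(n)) 100 * n / sum(n) else rep(0, length(n)),
               stringsAsFactors = FALSE)
  }
  if (is.null(by)) return(one(t_local))
  do.call(rbind, c(lapply(split(seq_along(t_local), by), function(i) {
    d <- one(t_local[i])
    d$group <- by[i[1]]
    d
  }), make.row.names = FALSE))
}
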