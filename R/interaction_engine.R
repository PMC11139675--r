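# Detection and aggregation of tarmacked-area interactions: one event per
# (movement step, tarmacked polygon) pair whose geometries intersect.

#' Season label for a local date
#'
#' Meteorological seasons: winter = Dec-Feb, spring = Mar-May,
#' summer = Jun-Aug, autumn = Sep-Nov.
#'
#' @param date Date vector (local civil dates).
#' @return Character vector of season labels.
#' @export
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  c("winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "autumn", "autumn", "autumn", "winter")[m]
}

#' Detect step-tarmac interactions
#'
#' For every non-degenerate movement step, emits one `InteractionEvent` per
#' tarmacked polygon whose closed region intersects the step segment
#' (boundary contact counts; a segment entering, leaving and re-entering the
#' same polygon still counts once for that polygon, but a step crossing two
#' tarmacked surfaces yields two events). Events are ordered by
#' (animal, time, surface id).
#'
#' @param steps data.frame from [build_steps()] / [build_steps_all()].
#' @param map A validated `surface_map`; its tarmacked subset must be
#'   non-empty.
#' @return data.frame of events with local timestamps, date, month
#'   (`"YYYY-MM"`), month number and season.
#' @export
detect_interactions <- function(steps, map) {
  stopifnot(inherits(map, "surface_map"))
  tar <- tarmacked_subset(map)
  if (length(tar$polygons) == 0) stop("surface map has no tarmacked polygons")
  live <- steps[!steps$degenerate, , drop = FALSE]
  ev <- list()
  for (p in tar$polygons) {
    hit <- if (nrow(live)) {
      segment_intersects_polygon(live$x0, live$y0, live$x1, live$y1, p$geometry)
    } else logical(0)
    if (any(hit)) {
      s <- live[hit, , drop = FALSE]
      ev[[length(ev) + 1]] <- data.frame(
        animal_id = s$animal_id,
        t_event = s$t_event,
        t_local = s$t_local,
        surface_id = p$surface_id,
        habitat_class = p$habitat_class,
        activity_status = p$activity_status,
        label = p$label,
        step_length_m = s$length_m,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(ev)) do.call(rbind, c(ev, make.row.names = FALSE)) else
    data.frame(animal_id = character(), t_event = as.POSIXct(character(), tz = "UTC"),
               t_local = as.POSIXct(character(), tz = "UTC"),
               surface_id = character(), habitat_class = character(),
               activity_status = character(), label = character(),
               step_length_m = numeric(), stringsAsFactors = FALSE)
  if (nrow(out)) {
    tz <- attr(steps$t_local, "tzone")
    out$date <- as.Date(format(out$t_local, "%Y-%m-%d"))
    out$month <- format(out$t_local, "%Y-%m")
    out$month_num <- as.integer(format(out$t_local, "%m"))
    out$season <- season_of(out$date)
    out <- out[order(out$animal_id, out$t_event, out$surface_id), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out$date <- as.Date(character())
    out$month <- character()
    out$month_num <- integer()
    out$season <- character()
  }
  out
}

#' Daily interaction counts per animal
#'
#' Counts events per animal per local day over each animal's deployment
#' interval, zero-filling days without events, and derives the per-animal
#' daily rate (total events / deployment days).
#'
#' @param events data.frame from [detect_interactions()].
#' @param trajectories `trajectory_set` (or list of trajectories) supplying
#'   deployment intervals; when `NULL`, the span of observed event dates per
#'   animal is used.
#' @return A list with `daily` (animal_id, date, n) and `rates`
#'   (animal_id, n_events, n_days, rate_per_day).
#' @export
daily_counts <- function(events, trajectories = NULL) {
  spans <- if (!is.null(trajectories)) {
    s <- lapply(trajectories, function(tr) {
      tz <- tr$tz
      seq(as.Date(format(to_local_time(tr$deploy_start, tz), "%Y-%m-%d")),
          as.Date(format(to_local_time(tr$deploy_end, tz), "%Y-%m-%d")),
          by = "day")
    })
    names(s) <- vapply(trajectories, `[[`, "", "animal_id")
    s
  } else {
    lapply(split(events$date, events$animal_id), function(d) {
      seq(min(d), max(d), by = "day")
    })
  }
  daily <- do.call(rbind, c(lapply(names(spans), function(id) {
    days <- spans[[id]]
    n <- table(factor(as.character(events$date[events$animal_id == id]),
                      levels = as.character(days)))
    data.frame(animal_id = id, date = days, n = as.integer(n),
               stringsAsFactors = FALSE)
  }), make.row.names = FALSE))
  rates <- do.call(rbind, c(lapply(split(daily, daily$animal_id), function(d) {
    data.frame(animal_id = d$animal_id[1], n_events = sum(d$n),
               n_days = nrow(d), rate_per_day = sum(d$n) / nrow(d),
               stringsAsFactors = FALSE)
    }), make.row.names = FALSE))
  list(daily = daily, rates = rates)
}

#' Monthly interaction summary
#'
#' Per calendar month: total events, mean per animal (total divided by the
#' number of collared animals, not the number present that month) and the
#' min-max range of per-animal totals.
#'
#' @param events Events data.frame.
#' @param n_animals Number of collared animals (> 0).
#' @param exclude_months Integer month numbers to drop (default 7, i.e. July).
#' @return data.frame (month, total, mean, min, max).
#' @export
monthly_summary <- function(events, n_animals, exclude_months = integer()) {
  stopifnot(n_animals > 0)
  ev <- events[!(events$month_num %in% exclude_months), , drop = FALSE]
  if (!nrow(ev)) {
    return(data.frame(month = character(), total = integer(), mean = numeric(),
                      min = integer(), max = integer()))
  }
  months <- sort(unique(ev$month))
  do.call(rbind, c(lapply(months, function(m) {
    em <- ev[ev$month == m, , drop = FALSE]
    per <- table(factor(em$animal_id, levels = unique(ev$animal_id)))
    data.frame(month = m, total = nrow(em), mean = nrow(em) / n_animals,
               min = min(per), max = max(per), stringsAsFactors = FALSE)
  }), make.row.names = FALSE))
}

#' Interaction counts and shares by surface category
#'
#' @param events Events data.frame.
#' @return A list with `by_class` (habitat class, n, pct of all events) and
#'   `by_surface` (class, label, n, pct within class).
#' @export
category_breakdown <- function(events) {
  n_all <- nrow(events)
  cls <- table(events$habitat_class)
  by_class <- data.frame(habitat_class = names(cls), n = as.integer(cls),
                         pct = if (n_all) 100 * as.integer(cls) / n_all else numeric(length(cls)),
                         stringsAsFactors = FALSE)
  key <- paste(events$habitat_class, events$label, sep = "\r")
  srf <- table(key)
  parts <- strsplit(names(srf), "\r", fixed = TRUE)
  by_surface <- data.frame(
    habitat_class = vapply(parts, `[`, "", 1),
    label = vapply(parts, `[`, "", 2),
    n = as.integer(srf), stringsAsFactors = FALSE)
  by_surface$pct_within_class <- 100 * by_surface$n /
    as.integer(cls[by_surface$habitat_class])
  list(by_class = by_class[order(-by_class$n), , drop = FALSE],
       by_surface = by_surface[order(by_surface$habitat_class, -by_surface$n), ,
                               drop = FALSE])
}

#' Extrapolate interaction pressure to a population
#'
#' Scales a per-animal daily interaction rate to population level and, given
#' a mean event duration, to total daily tarmac occupancy (assuming
#' non-concurrent interactions).
#'
#' @param mean_rate_per_animal_day Mean interactions per animal per day.
#' @param population_size Estimated population size.
#' @param mean_event_duration_s Mean duration of one interaction, seconds.
#' @return A list: `interactions_per_day`, `occupancy_s`, `occupancy_h`.
#' @export
population_extrapolation <- function(mean_rate_per_animal_day, population_size,
                                     mean_event_duration_s = NA_real_) {
  stopifnot(mean_rate_per_animal_day >= 0, population_size >= 0)
  daily <- mean_rate_per_animal_day * population_size
  occ_s <- daily * mean_event_duration_s
  list(interactions_per_day = daily,
       occupancy_s = occ_s,
       occupancy_h = occ_s / 3600)
}

#' Trimmed mean dwell time
#'
#' Mean duration after removing listed outlying observations from a sample
#' summarised by its size and mean (used for tarmac dwell times where a few
#' resting bouts dominate an otherwise short-visit distribution).
#'
#' @param n Sample size.
#' @param mean_s Sample mean (seconds).
#' @param exclude_s Durations (seconds) of the observations to remove.
#' @return Trimmed mean in seconds.
#' @export
trimmed_mean_dwell <- function(n, mean_s, exclude_s = numeric()) {
  stopifnot(n > length(exclude_s))
  (n * mean_s - sum(exclude_s)) / (n - length(exclude_s))
}
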