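# Reading Movebank-style GPS fix tables, quality control and step building.

.parse_utc <- function(x) {
  x <- trimws(as.character(x))
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  miss <- is.na(t)
  if (any(miss)) {
    t[miss] <- as.POSIXct(x[miss], format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
  }
  t
}

.default_cols <- list(animal_id = "animal_id", timestamp = "timestamp",
                      lon = "lon", lat = "lat", h_accuracy = "h_accuracy")

#' Read a GPS fix table into per-animal trajectories
#'
#' Reads a comma-separated fix table (one row per GPS fix: animal identifier,
#' ISO-8601 UTC timestamp, longitude, latitude, horizontal accuracy in metres),
#' converts timestamps to the study's civil time zone, projects coordinates to
#' a local metric transverse-Mercator frame, and returns one [`trajectory`]
#' per animal with fixes sorted in time.
#'
#' Rows whose timestamp cannot be parsed are dropped; the number dropped is
#' reported via `message()` and stored in the `n_rejected` attribute.
#'
#' @param path Path to the CSV file.
#' @param tz IANA time-zone identifier for civil local time
#'   (default `"Europe/Dublin"`).
#' @param proj Optional `tm_projection`; when `NULL`, a frame centred on the
#'   mean fix position is created.
#' @param col_map Named list mapping the roles `animal_id`, `timestamp`,
#'   `lon`, `lat`, `h_accuracy` to column names in the file.
#' @return A named list of `trajectory` objects (class `trajectory_set`).
#' @export
read_gps_table <- function(path, tz = "Europe/Dublin", proj = NULL,
                           col_map = list()) {
  cols <- utils::modifyList(.default_cols, col_map)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- unlist(cols[c("animal_id", "timestamp", "lon", "lat")])
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("fix table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  has_acc <- cols$h_accuracy %in% names(df)
  t_utc <- .parse_utc(df[[cols$timestamp]])
  bad <- is.na(t_utc)
  if (any(bad)) {
    message(sum(bad), " row(s) with unparseable timestamps rejected")
    df <- df[!bad, , drop = FALSE]
    t_utc <- t_utc[!bad]
  }
  if (nrow(df) == 0) {
    out <- structure(list(), class = "trajectory_set")
    attr(out, "n_rejected") <- sum(bad)
    return(out)
  }
  lon <- as.numeric(df[[cols$lon]])
  lat <- as.numeric(df[[cols$lat]])
  if (is.null(proj)) proj <- make_projection(mean(lon), mean(lat))
  xy <- project_lonlat(lon, lat, proj)
  acc <- if (has_acc) as.numeric(df[[cols$h_accuracy]]) else rep(NA_real_, nrow(df))
  ids <- as.character(df[[cols$animal_id]])
  out <- lapply(split(seq_along(ids), ids), function(i) {
    o <- i[order(t_utc[i])]
    fixes <- data.frame(
      animal_id = ids[o],
      t_utc = t_utc[o],
      x = xy$x[o], y = xy$y[o],
      lon = lon[o], lat = lat[o],
      h_accuracy = acc[o],
      stringsAsFactors = FALSE
    )
    new_trajectory(fixes, tz = tz, proj = proj)
  })
  structure(out, class = "trajectory_set", n_rejected = sum(bad))
}

#' Construct a trajectory from a fix table
#'
#' @param fixes data.frame with columns `animal_id`, `t_utc` (POSIXct, UTC),
#'   `x`, `y` (m), optionally `lon`, `lat`, `h_accuracy`.
#' @param tz Civil time zone.
#' @param proj Optional `tm_projection` used for the planar frame.
#' @param deploy_start,deploy_end Deployment dates; default to the first/last
#'   fix timestamps.
#' @return An object of class `trajectory`.
#' @export
new_trajectory <- function(fixes, tz = "Europe/Dublin", proj = NULL,
                           deploy_start = NULL, deploy_end = NULL) {
  stopifnot(all(c("animal_id", "t_utc", "x", "y") %in% names(fixes)))
  if (!tz %in% OlsonNames()) stop("unknown time zone: ", tz)
  if (is.unsorted(as.numeric(fixes$t_utc))) {
    fixes <- fixes[order(fixes$t_utc), , drop = FALSE]
  }
  if (!"h_accuracy" %in% names(fixes)) fixes$h_accuracy <- NA_real_
  if (is.null(deploy_start)) deploy_start <- min(fixes$t_utc)
  if (is.null(deploy_end)) deploy_end <- max(fixes$t_utc)
  structure(list(
    animal_id = fixes$animal_id[1],
    fixes = fixes,
    deploy_start = deploy_start,
    deploy_end = deploy_end,
    tz = tz,
    proj = proj
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory %s: %d fixes, %s to %s (%s)\n", x$animal_id,
              nrow(x$fixes),
              format(x$deploy_start, "%Y-%m-%d"),
              format(x$deploy_end, "%Y-%m-%d"), x$tz))
  invisible(x)
}

#' Convert a UTC instant to civil local time
#'
#' Returns the same instant with its display zone set to `zone`, so formatted
#' output (and `as.POSIXlt` fields) reflect DST-aware civil time.
#'
#' @param t_utc POSIXct vector (UTC).
#' @param zone IANA zone identifier, e.g. `"Europe/Dublin"`.
#' @return POSIXct vector with `tzone = zone`.
#' @export
to_local_time <- function(t_utc, zone) {
  if (!zone %in% OlsonNames()) stop("unknown time zone: ", zone)
  lt <- t_utc
  attr(lt, "tzone") <- zone
  lt
}

#' Quality-filter a trajectory
#'
#' Removes fixes with horizontal accuracy strictly greater than
#' `max_accuracy_m` (30 m default; fixes with missing accuracy are retained)
#' and fixes within the post-capture burn-in window of `burn_in_days` whole
#' days from `deploy_start`. Removal counts by reason are attached as the
#' `removed` attribute.
#'
#' @param traj A `trajectory`.
#' @param max_accuracy_m Accuracy threshold in metres (> 0).
#' @param burn_in_days Days removed from the start of deployment.
#' @return The filtered `trajectory` (possibly with zero fixes, with warning).
#' @export
filter_fixes <- function(traj, max_accuracy_m = 30, burn_in_days = 5) {
  stopifnot(inherits(traj, "trajectory"), max_accuracy_m > 0, burn_in_days >= 0)
  f <- traj$fixes
  bad_acc <- !is.na(f$h_accuracy) & f$h_accuracy > max_accuracy_m
  cutoff <- traj$deploy_start + burn_in_days * 86400
  bad_burn <- f$t_utc < cutoff
  keep <- !bad_acc & !bad_burn
  out <- traj
  out$fixes <- f[keep, , drop = FALSE]
  attr(out, "removed") <- c(accuracy = sum(bad_acc & !bad_burn),
                            burn_in = sum(bad_burn))
  if (!any(keep)) warning("all fixes removed for animal ", traj$animal_id)
  out
}

#' Build movement steps from consecutive fixes
#'
#' A trajectory of n fixes yields n - 1 steps, each the straight segment
#' between consecutive fixes. Steps with identical endpoints are retained but
#' flagged `degenerate` (they are excluded from intersection tests). Each
#' step's event time `t_event` is the timestamp of its earlier fix.
#'
#' @param traj A `trajectory` (ideally after [filter_fixes()]).
#' @param max_duration_h Optional: steps longer than this many hours are
#'   flagged in the `long_gap` column (never dropped). `NULL` disables.
#' @return data.frame of steps with planar endpoints, `length_m`,
#'   `duration_s`, `t_event` (UTC) and `t_local`.
#' @export
build_steps <- function(traj, max_duration_h = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  f <- traj$fixes
  n <- nrow(f)
  if (n < 2) {
    return(data.frame(animal_id = character(), t_event = as.POSIXct(character(), tz = "UTC"),
                      x0 = numeric(), y0 = numeric(), x1 = numeric(), y1 = numeric(),
                      length_m = numeric(), duration_s = numeric(),
                      degenerate = logical(), long_gap = logical()))
  }
  i <- seq_len(n - 1)
  len <- sqrt((f$x[i + 1] - f$x[i])^2 + (f$y[i + 1] - f$y[i])^2)
  dur <- as.numeric(difftime(f$t_utc[i + 1], f$t_utc[i], units = "secs"))
  steps <- data.frame(
    animal_id = f$animal_id[i],
    t_event = f$t_utc[i],
    x0 = f$x[i], y0 = f$y[i], x1 = f$x[i + 1], y1 = f$y[i + 1],
    length_m = len,
    duration_s = dur,
    degenerate = len == 0,
    long_gap = if (is.null(max_duration_h)) FALSE else dur > max_duration_h * 3600,
    stringsAsFactors = FALSE
  )
  steps$t_local <- to_local_time(steps$t_event, traj$tz)
  steps
}

#' Build steps for every animal in a trajectory set
#'
#' @param trajs A `trajectory_set` or list of `trajectory` objects.
#' @param ... Passed to [build_steps()].
#' @return A single data.frame of steps across animals.
#' @export
build_steps_all <- function(trajs, ...) {
  do.call(rbind, c(lapply(trajs, build_steps, ...), make.row.names = FALSE))
}
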