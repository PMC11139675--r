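# Shared fixtures, built in code. The study-like scenario and its pipeline
# run are expensive, so they are computed once per session on demand.

.cache <- new.env(parent = emptyenv())

cached_scenario <- function(seed = 42) {
  key <- paste0("scenario_", seed)
  if (is.null(.cache[[key]])) .cache[[key]] <- scenario_paper_like(seed)
  .cache[[key]]
}

cached_run <- function(seed = 42) {
  key <- paste0("run_", seed)
  if (is.null(.cache[[key]])) {
    b <- cached_scenario(seed)
    .cache[[key]] <- run_pipeline(b$fixes_csv, b$map_geojson,
                                  keep_partial_months = c("2021-12", "2022-01"))
  }
  .cache[[key]]
}

# Axis-aligned rectangle vertex matrix.
rect_poly <- function(cx, cy, w, h) {
  cbind(c(cx - w / 2, cx + w / 2, cx + w / 2, cx - w / 2),
        c(cy - h / 2, cy - h / 2, cy + h / 2, cy + h / 2))
}

# Minimal surface map: one runway (60 m wide), one parallel taxiway (35 m),
# one grassland island well away from both.
toy_map <- function() {
  new_surface_map(list(
    list(surface_id = "rw1", geometry = rect_poly(0, 0, 2000, 60),
         habitat_class = "tarmac_runway", activity_status = "active",
         label = "09-27"),
    list(surface_id = "tw1", geometry = rect_poly(0, 150, 2000, 35),
         habitat_class = "tarmac_taxiway", activity_status = "active",
         label = "taxi-09-27"),
    list(surface_id = "gr1", geometry = rect_poly(0, -500, 2000, 400),
         habitat_class = "grassland", activity_status = "not_applicable",
         label = "grass")))
}

# Steps table from a coordinate path at fixed 10-min spacing.
path_steps <- function(xy, animal_id = "A",
                       t0 = as.POSIXct("2022-04-10 06:00:00", tz = "UTC"),
                       tz = "Europe/Dublin") {
  n <- nrow(xy)
  fixes <- data.frame(animal_id = animal_id,
                      t_utc = t0 + (seq_len(n) - 1) * 600,
                      x = xy[, 1], y = xy[, 2])
  build_steps(new_trajectory(fixes, tz = tz))
}

# Fix table CSV written to a temp file.
write_fix_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

solar_day_at <- function(sunrise, sunset, date = "2022-04-10",
                         tz = "Europe/Dublin") {
  structure(list(
    date = as.Date(date),
    sunrise_local = as.POSIXct(paste(date, sunrise), tz = tz),
    sunset_local = as.POSIXct(paste(date, sunset), tz = tz),
    daylight_h = as.numeric(difftime(
      as.POSIXct(paste(date, sunset), tz = tz),
      as.POSIXct(paste(date, sunrise), tz = tz), units = "hours"))),
    class = "solar_day")
}
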