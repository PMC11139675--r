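# End-to-end orchestration: ingest -> QC -> steps -> interactions -> solar
# offsets -> distances -> home ranges, with report tables mirroring the
# standard deployment / monthly / home-range summaries.

#' Run the full airside telemetry analysis
#'
#' Executes every pipeline stage on a fix table and surface map and returns
#' the three report tables (per-animal deployment summary, monthly
#' interaction summary, home-range habitat table) plus the underlying event
#' and distance data and the seasonal/monthly rank-test reports. When
#' `out_dir` is given, tables are written as CSV and test reports as JSON,
#' with a resolved-config echo and a processing log.
#'
#' @param gps_csv Path to the fix table CSV ([read_gps_table()] dialect).
#' @param map_geojson Path to the surface-map GeoJSON.
#' @param tz Civil time zone.
#' @param lat,lon Site coordinates for solar computations.
#' @param max_accuracy_m,burn_in_days Quality-control thresholds.
#' @param exclude_months Month numbers excluded from monthly summaries and
#'   the month-wise distance test.
#' @param kud_level Home-range probability level.
#' @param kud_grid_n KUD grid resolution per axis.
#' @param keep_partial_months `"YYYY-MM"` months exempt from the
#'   full-calendar-month rule in cumulative distances.
#' @param solar_lookup Optional sunrise/sunset lookup table.
#' @param out_dir Optional output directory.
#' @return A list of class `airside_run` with elements `table1`, `table2`,
#'   `table3`, `events`, `offsets`, `daily_counts`, `daily_distance`,
#'   `monthly_distance`, `season_test`, `month_test`, `category`,
#'   `step_summary`, `home_ranges`, `log`.
#' @export
run_pipeline <- function(gps_csv, map_geojson, tz = "Europe/Dublin",
                         lat = 53.43, lon = -6.25,
                         max_accuracy_m = 30, burn_in_days = 5,
                         exclude_months = 7, kud_level = 0.95,
                         kud_grid_n = 200,
                         keep_partial_months = character(),
                         solar_lookup = NULL, out_dir = NULL) {
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  trajs <- read_gps_table(gps_csv, tz = tz)
  if (!length(trajs)) stop("ingest: no trajectories read from ", gps_csv)
  note("ingest: %d animals, %d fixes, %d rows rejected", length(trajs),
       sum(vapply(trajs, function(t) nrow(t$fixes), 0)),
       attr(trajs, "n_rejected"))
  proj <- trajs[[1]]$proj

  filtered <- lapply(trajs, filter_fixes, max_accuracy_m = max_accuracy_m,
                     burn_in_days = burn_in_days)
  for (tr in filtered) {
    rm_ <- attr(tr, "removed")
    note("filter %s: %d accuracy > %g m, %d burn-in", tr$animal_id,
         rm_["accuracy"], max_accuracy_m, rm_["burn_in"])
  }

  steps <- build_steps_all(filtered)
  note("steps: %d (%d degenerate)", nrow(steps), sum(steps$degenerate))

  map <- load_surface_map(map_geojson, proj = proj)
  events <- detect_interactions(steps, map)
  note("interactions: %d events on %d surfaces", nrow(events),
       length(unique(events$surface_id)))

  dc <- daily_counts(events, filtered)
  n_animals <- length(filtered)
  table2 <- monthly_summary(events, n_animals, exclude_months = exclude_months)
  cat_bd <- category_breakdown(events)

  offsets <- event_offsets(events, lat, lon, tz = tz, lookup = solar_lookup)
  season_test <- tryCatch(
    seasonal_offset_comparison(offsets$offset_h, offsets$season),
    error = function(e) {
      note("season test skipped: %s", conditionMessage(e))
      NULL
    })

  dd <- daily_distance(steps)
  md <- monthly_cumulative(dd, keep_partial = keep_partial_months)
  month_test <- tryCatch(monthly_distance_test(dd, exclude_months = exclude_months),
                         error = function(e) {
                           note("month test skipped: %s", conditionMessage(e))
                           NULL
                         })
  ssum <- step_length_summary(steps)

  hr <- home_range_table(filtered, map, level = kud_level, grid_n = kud_grid_n)

  n_fixes <- vapply(filtered, function(t) nrow(t$fixes), 0)
  n_events <- vapply(names(filtered), function(id) {
    sum(events$animal_id == id)
  }, 0)
  table1 <- data.frame(
    animal_id = names(filtered),
    n_days = dc$rates$n_days[match(names(filtered), dc$rates$animal_id)],
    n_fixes = as.integer(n_fixes),
    n_interactions = as.integer(n_events),
    pct_fixes_interacting = round(100 * n_events / n_fixes, 1),
    rate_per_day = dc$rates$rate_per_day[match(names(filtered), dc$rates$animal_id)],
    stringsAsFactors = FALSE)
  rownames(table1) <- NULL

  res <- structure(list(
    table1 = table1, table2 = table2, table3 = hr$table,
    events = events, offsets = offsets, daily_counts = dc,
    daily_distance = dd, monthly_distance = md,
    season_test = season_test, month_test = month_test,
    category = cat_bd, step_summary = ssum,
    home_ranges = hr$home_ranges, log = log), class = "airside_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table1, file.path(out_dir, "table1_animals.csv"), row.names = FALSE)
    utils::write.csv(table2, file.path(out_dir, "table2_monthly.csv"), row.names = FALSE)
    utils::write.csv(hr$table, file.path(out_dir, "table3_home_ranges.csv"), row.names = FALSE)
    ev_out <- events
    ev_out$t_local <- format(ev_out$t_local, "%Y-%m-%dT%H:%M:%S")
    ev_out$t_event <- format(ev_out$t_event, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    utils::write.csv(ev_out, file.path(out_dir, "events.csv"), row.names = FALSE)
    utils::write.csv(dd, file.path(out_dir, "daily_distance.csv"), row.names = FALSE)
    reports <- list(
      season_test = if (!is.null(season_test)) list(
        H = season_test$kw$H, df = season_test$kw$df, p = season_test$kw$p,
        dunn = season_test$dunn, summary = season_test$summary),
      month_test = if (!is.null(month_test)) list(
        H = month_test$kw$H, df = month_test$kw$df, p = month_test$kw$p,
        dunn = month_test$dunn),
      config = list(tz = tz, lat = lat, lon = lon,
                    max_accuracy_m = max_accuracy_m,
                    burn_in_days = burn_in_days,
                    exclude_months = exclude_months, kud_level = kud_level))
    jsonlite::write_json(reports, file.path(out_dir, "reports.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log, file.path(out_dir, "run.log"))
  }
  res
}

#' @export
print.airside_run <- function(x, ...) {
  cat("Airside telemetry run:", nrow(x$table1), "animals,",
      nrow(x$events), "tarmac interactions\n")
  print(x$table1)
  invisible(x)
}

#' Internal-consistency checks of report tables
#'
#' Asserts the arithmetic identities that must hold between report tables:
#' the grand interaction total equals the per-animal sum and the per-category
#' sum, monthly means equal total / n-animals, per-animal interaction
#' percentages follow from counts, and the per-day sums reconcile with
#' per-animal totals. Failures are returned as data, not raised.
#'
#' @param run An `airside_run` from [run_pipeline()].
#' @return data.frame (check, pass, detail).
#' @export
report_consistency_check <- function(run) {
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1]] <<- data.frame(check = name, pass = pass,
                                                detail = detail,
                                                stringsAsFactors = FALSE)
  }
  tot <- nrow(run$events)
  add("total = sum per animal", sum(run$table1$n_interactions) == tot,
      sprintf("%d vs %d", sum(run$table1$n_interactions), tot))
  add("total = sum per category", sum(run$category$by_class$n) == tot,
      sprintf("%d vs %d", sum(run$category$by_class$n), tot))
  add("total = sum per day", sum(run$daily_counts$daily$n) == tot,
      sprintf("%d vs %d", sum(run$daily_counts$daily$n), tot))
  n_anim <- nrow(run$table1)
  if (nrow(run$table2)) {
    ok <- all(abs(run$table2$mean - run$table2$total / n_anim) < 1e-9)
    add("monthly mean = total / n_animals", ok)
  }
  pct <- round(100 * run$table1$n_interactions / run$table1$n_fixes, 1)
  add("pct column = interactions / fixes * 100",
      all(abs(pct - run$table1$pct_fixes_interacting) < 1e-9))
  if (nrow(run$category$by_class)) {
    add("category percentages sum to 100",
        abs(sum(run$category$by_class$pct) - 100) < 1e-6)
  }
  do.call(rbind, c(checks, make.row.names = FALSE))
}
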