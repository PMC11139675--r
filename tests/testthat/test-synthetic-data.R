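test_that("synthetic airfield has the required surfaces and exact widths", {
  m <- make_airfield(seed = 3)
  classes <- vapply(m$polygons, `[[`, "", "habitat_class")
  expect_true(all(c("tarmac_runway", "tarmac_taxiway", "tarmac_connecting",
                    "apron", "built_land", "grassland", "service_road",
                    "unknown") %in% classes))
  rw <- m$polygons[[which(classes == "tarmac_runway")[1]]]$geometry
  tw <- m$polygons[[which(classes == "tarmac_taxiway")[1]]]$geometry
  expect_equal(diff(range(rw[, 2])), 60)   # runway width
  expect_equal(diff(range(tw[, 2])), 35)   # taxiway width
  expect_silent(validate_surface_map(m))
})

test_that("airfield and simulation are byte-identical under a fixed seed", {
  f1 <- tempfile(fileext = ".geojson")
  f2 <- tempfile(fileext = ".geojson")
  write_surface_map(make_airfield(seed = 11), f1)
  write_surface_map(make_airfield(seed = 11), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(readLines(f1),
                         {f3 <- tempfile(); write_surface_map(make_airfield(seed = 12), f3); readLines(f3)}))
  b <- cached_scenario(42)
  sim2 <- simulate_hares(b$map, b$sim$cfg, seed = 42)
  expect_identical(sim2$fixes, b$sim$fixes)
  expect_identical(sim2$truth$crossings, b$sim$truth$crossings)
})

test_that("fix schedule is 10 min when active and up to 6 h at rest", {
  b <- cached_scenario(42)
  fx <- b$sim$fixes[b$sim$fixes$animal_id == "S3", ]
  t <- as.POSIXct(fx$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  iv <- diff(as.numeric(t))
  expect_true(all(iv >= 600))
  expect_true(all(iv <= 6 * 3600))
  # the modal interval is the active 10-min schedule
  expect_equal(as.integer(names(which.max(table(iv)))), 600)
  # long resting gaps hit the 6 h fallback exactly
  expect_true(any(iv == 6 * 3600))
})

test_that("simulated activity is crepuscular around sunrise and sunset", {
  b <- cached_scenario(42)
  fx <- b$sim$fixes[b$sim$fixes$state == "active", ]
  t_loc <- to_local_time(as.POSIXct(fx$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                                    tz = "UTC"), "Europe/Dublin")
  h <- clock_histogram(t_loc, bin_h = 1)
  # December in Dublin: sunrise ~08:40, sunset ~16:10 local
  dawn <- sum(h$pct[h$start_h %in% 7:10])
  dusk <- sum(h$pct[h$start_h %in% 14:17])
  troughs <- sum(h$pct[h$start_h %in% c(0:4, 11:12, 20:23)])
  expect_gt(dawn / 4, troughs / 11)       # per-hour activity higher at dawn
  expect_gt(dusk / 4, troughs / 11)
  # the two busiest hours straddle the two sun events (within 2 h)
  top2 <- h$start_h[order(-h$pct)][1:2]
  expect_true(any(abs(top2 - 8.7) <= 2))
  expect_true(any(abs(top2 - 16.2) <= 2))
})

test_that("true daily path length bounds the fix-based daily distance", {
  b <- cached_scenario(42)
  trajs <- read_gps_table(b$fixes_csv)
  dd <- daily_distance(build_steps_all(trajs))
  truth <- b$sim$truth$daily_path_km
  merged <- merge(dd, truth, by = c("animal_id", "date"))
  expect_gt(nrow(merged), 100)
  expect_true(all(merged$path_km >= merged$distance_km - 0.05))
  # and the bulk of days are strictly under-measured by the fix polyline
  expect_gt(mean(merged$path_km > merged$distance_km), 0.95)
})

test_that("an attracted, noise-free animal far from tarmac never crosses", {
  m <- make_airfield(seed = 5)
  animals <- data.frame(animal_id = "Z1", x0 = 0, y0 = -400, attract = 0.05,
                        speed_m_min = 4, excursion_per_day = 0,
                        excursion_mode = "touch", stringsAsFactors = FALSE)
  cfg <- sim_config(animals, days = 6, gps_noise_sd = 0, frac_bad_acc = 0)
  sim <- simulate_hares(m, cfg, seed = 6)
  expect_equal(nrow(sim$truth$crossings), 0)
  trajs <- read_gps_table(write_fixes_csv(sim$fixes, tempfile(fileext = ".csv")))
  ev <- detect_interactions(build_steps_all(trajs), m)
  expect_equal(nrow(ev), 0)
  # too-short periods are rejected (burn-in would consume them)
  expect_error(simulate_hares(m, sim_config(animals, days = 4), seed = 1),
               "burn-in")
})

test_that("a scripted two-fix crossing yields one truth crossing and one event", {
  m <- toy_map()
  st <- path_steps(rbind(c(0, -100), c(0, 100)))
  ev <- detect_interactions(st, m)
  expect_equal(nrow(ev), 1)
  # the same chord sampled densely crosses the runway region exactly once
  tt <- seq(0, 1, length.out = 2001)
  inside <- point_in_polygon(0 * tt, -100 + 200 * tt,
                             m$polygons[[1]]$geometry)
  runs <- rle(inside)
  expect_equal(sum(runs$values), 1)
})

test_that("zero-noise fixes inside a truth crossing are always detected", {
  m <- make_airfield(seed = 7)
  animals <- data.frame(animal_id = "Z2", x0 = -200, y0 = 620, attract = 0.003,
                        speed_m_min = 7, excursion_per_day = 2,
                        excursion_mode = "through", stringsAsFactors = FALSE)
  cfg <- sim_config(animals, days = 8, gps_noise_sd = 0, frac_bad_acc = 0)
  sim <- simulate_hares(m, cfg, seed = 8)
  trajs <- read_gps_table(write_fixes_csv(sim$fixes, tempfile(fileext = ".csv")),
                          proj = sim$proj)
  steps <- build_steps_all(lapply(trajs, filter_fixes, burn_in_days = 0))
  ev <- detect_interactions(steps, m)
  fix_t <- as.POSIXct(sim$fixes$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                      tz = "UTC")
  cr <- sim$truth$crossings
  witnessed <- vapply(seq_len(nrow(cr)), function(i) {
    any(fix_t >= cr$t_enter[i] & fix_t <= cr$t_exit[i])
  }, TRUE)
  expect_gt(sum(witnessed), 0)
  recalled <- vapply(which(witnessed), function(i) {
    any(ev$surface_id == cr$surface_id[i] &
          abs(as.numeric(difftime(ev$t_event, cr$t_enter[i], units = "hours"))) <= 6)
  }, TRUE)
  expect_true(all(recalled))   # 100% recall on fix-witnessed crossings
})

test_that("the study-like scenario is reproducible and structurally sound", {
  b <- cached_scenario(42)
  expect_equal(sort(unique(b$sim$fixes$animal_id)), c("S1", "S2", "S3", "S4", "S5"))
  expect_true(file.exists(b$fixes_csv))
  expect_true(file.exists(b$map_geojson))
  # ~2% of fixes carry accuracy above the 30 m QC threshold
  expect_equal(mean(b$sim$fixes$h_accuracy > 30), 0.02, tolerance = 0.5)
  # truth log crossings lie on tarmacked surfaces only
  tar_ids <- vapply(tarmacked_subset(b$map)$polygons, `[[`, "", "surface_id")
  expect_true(all(b$sim$truth$crossings$surface_id %in% tar_ids))
})
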