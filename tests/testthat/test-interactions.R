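test_that("interaction detection: crossings, multi-surface steps, non-events", {
  m <- toy_map()
  # one step straight across the runway (60 m wide, centred on y = 0)
  st <- path_steps(rbind(c(0, -100), c(0, 100)))
  ev <- detect_interactions(st, m)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$surface_id, "rw1")
  expect_equal(ev$habitat_class, "tarmac_runway")
  expect_equal(ev$t_event, st$t_event[1], ignore_attr = "tzone")
  # one step crossing runway then its parallel taxiway: two events
  ev2 <- detect_interactions(path_steps(rbind(c(0, -100), c(0, 200))), m)
  expect_equal(nrow(ev2), 2)
  expect_setequal(ev2$surface_id, c("rw1", "tw1"))
  # wholly within grassland: no events
  ev3 <- detect_interactions(path_steps(rbind(c(0, -600), c(100, -450))), m)
  expect_equal(nrow(ev3), 0)
  # boundary graze counts; degenerate steps are skipped
  ev4 <- detect_interactions(path_steps(rbind(c(-10, 30), c(10, 30))), m)
  expect_equal(nrow(ev4), 1)
  ev5 <- detect_interactions(path_steps(rbind(c(0, 0), c(0, 0))), m)
  expect_equal(nrow(ev5), 0)
  # an in-and-out-and-in segment still counts once per polygon
  expect_error(detect_interactions(st, new_surface_map(toy_map()$polygons[3])),
               "no tarmacked polygons")
})

test_that("detection is translation-invariant and monotone in added surfaces", {
  set.seed(9)
  xy <- cbind(cumsum(rnorm(80, sd = 60)), cumsum(rnorm(80, sd = 60)))
  st <- path_steps(xy)
  m <- toy_map()
  base <- detect_interactions(st, m)
  # shift everything by the same vector
  shift <- c(1234, -777)
  xy2 <- cbind(xy[, 1] + shift[1], xy[, 2] + shift[2])
  m2 <- m
  m2$polygons <- lapply(m$polygons, function(p) {
    p$geometry <- cbind(p$geometry[, 1] + shift[1], p$geometry[, 2] + shift[2])
    p
  })
  moved <- detect_interactions(path_steps(xy2), m2)
  expect_equal(nrow(moved), nrow(base))
  expect_equal(moved$surface_id, base$surface_id)
  # adding a tarmacked polygon never decreases the event count
  m3 <- m
  m3$polygons <- c(m3$polygons, list(
    list(surface_id = "tw2", geometry = rect_poly(0, -150, 2000, 35),
         habitat_class = "tarmac_taxiway", activity_status = "inactive",
         label = "tw2")))
  expect_gte(nrow(detect_interactions(st, m3)), nrow(base))
})

test_that("daily counts zero-fill deployment days and conserve totals", {
  m <- toy_map()
  t0 <- as.POSIXct("2022-04-10 06:00:00", tz = "UTC")
  xy <- rbind(c(0, -100), c(0, 100), c(0, -100), c(0, -120), c(0, -130))
  fixes <- data.frame(animal_id = "a", t_utc = t0 + (0:4) * 600,
                      x = xy[, 1], y = xy[, 2])
  tr <- new_trajectory(fixes, deploy_start = t0,
                       deploy_end = t0 + 2 * 86400)  # 3-day deployment
  ev <- detect_interactions(build_steps(tr), m)
  dc <- daily_counts(ev, list(tr))
  expect_equal(nrow(dc$daily), 3)                    # every day present
  expect_equal(sum(dc$daily$n), nrow(ev))
  expect_equal(dc$daily$n[2:3], c(0, 0))
  expect_equal(dc$rates$rate_per_day, nrow(ev) / 3)
  # no events at all -> zero rate
  none <- detect_interactions(path_steps(rbind(c(0, -600), c(0, -610))), m)
  dc0 <- daily_counts(none, list(tr))
  expect_equal(dc0$rates$rate_per_day, 0)
})

mk_events <- function(animal, month_num, class = "tarmac_runway",
                      label = "09-27", n = 1) {
  data.frame(animal_id = rep(animal, n),
             month = sprintf("2022-%02d", month_num),
             month_num = month_num, habitat_class = class, label = label,
             stringsAsFactors = FALSE)
}

test_that("monthly summary divides by collar count and honours exclusions", {
  ev <- rbind(mk_events("a", 4, n = 700), mk_events("b", 4, n = 373),
              mk_events("a", 7, n = 10), mk_events("b", 12, n = 583))
  ev$month[ev$month_num == 12] <- "2021-12"
  ms <- monthly_summary(ev, n_animals = 5, exclude_months = 7)
  expect_equal(ms$total[ms$month == "2022-04"], 1073)
  expect_equal(ms$mean[ms$month == "2022-04"], 214.6)
  expect_equal(ms$total[ms$month == "2021-12"], 583)
  expect_equal(ms$mean[ms$month == "2021-12"], 116.6)
  expect_false("2022-07" %in% ms$month)
  expect_equal(ms$min[ms$month == "2022-04"], 373)
  expect_equal(ms$max[ms$month == "2022-04"], 700)
  expect_error(monthly_summary(ev, n_animals = 0), "n_animals > 0")
})

test_that("category breakdown computes overall and within-class shares", {
  ev <- rbind(
    mk_events("a", 4, "tarmac_runway", "16-34", 1564),
    mk_events("a", 4, "tarmac_runway", "10L-28R", 116),
    mk_events("a", 4, "tarmac_runway", "10R-28L", 26),
    mk_events("a", 4, "tarmac_taxiway", "t1", 2502),
    mk_events("a", 4, "tarmac_connecting", "c1", 363))
  cb <- category_breakdown(ev)
  runway <- cb$by_class[cb$by_class$habitat_class == "tarmac_runway", ]
  expect_equal(runway$n, 1706)
  expect_equal(round(runway$pct, 1), 37.3)
  expect_equal(round(cb$by_class$pct[cb$by_class$habitat_class == "tarmac_taxiway"], 1),
               54.7)
  main <- cb$by_surface[cb$by_surface$label == "16-34", ]
  expect_equal(round(main$pct_within_class, 1), 91.7)
  expect_equal(sum(cb$by_class$pct), 100)
  # single category: 100% for it
  one <- category_breakdown(mk_events("a", 1, n = 7))
  expect_equal(one$by_class$pct, 100)
})

test_that("population extrapolation scales rate and occupancy", {
  expect_equal(population_extrapolation(4.3, 118)$interactions_per_day, 507.4)
  expect_equal(population_extrapolation(0, 118)$interactions_per_day, 0)
  occ <- population_extrapolation(1, 10, mean_event_duration_s = 60)
  expect_equal(occ$occupancy_s, 600)
  expect_equal(occ$occupancy_h, 1 / 6)
})

test_that("season labels follow the meteorological convention", {
  expect_equal(season_of(as.Date(c("2021-12-05", "2022-02-28", "2022-03-01",
                                   "2022-06-15", "2022-09-01"))),
               c("winter", "winter", "spring", "summer", "autumn"))
})
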