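mk_rows <- function(id, times, lon = -6.25, lat = 53.43, acc = 5) {
  n <- length(id)
  data.frame(animal_id = id, timestamp = times,
             lon = rep_len(lon, n), lat = rep_len(lat, n),
             h_accuracy = rep_len(acc, n))
}

test_that("read_gps_table splits by animal, sorts in time, rejects bad rows", {
  # empty file with header
  empty <- write_fix_csv(mk_rows(character(), character()))
  expect_length(read_gps_table(empty), 0)
  # out-of-order rows are sorted; two animals split
  rows <- rbind(
    mk_rows("b", c("2022-01-01T10:00:00Z", "2022-01-01T08:00:00Z",
                   "2022-01-01T09:00:00Z")),
    mk_rows("a", sprintf("2022-01-01T%02d:00:00Z", 1:10)))
  trajs <- read_gps_table(write_fix_csv(rows))
  expect_named(trajs, c("a", "b"))
  expect_equal(nrow(trajs$a$fixes), 10)
  expect_false(is.unsorted(trajs$b$fixes$t_utc))
  # unparseable timestamps rejected with a message
  rows2 <- mk_rows("a", c("2022-01-01T08:00:00Z", "not-a-time"))
  expect_message(trajs2 <- read_gps_table(write_fix_csv(rows2)), "rejected")
  expect_equal(nrow(trajs2$a$fixes), 1)
  # schema error
  bad <- write_fix_csv(data.frame(animal_id = "a", lon = 1, lat = 2))
  expect_error(read_gps_table(bad), "missing mandatory column")
})

test_that("accuracy filter is strict at 30 m and keeps missing accuracy", {
  fixes <- data.frame(
    animal_id = "a",
    t_utc = as.POSIXct("2022-01-10 00:00", tz = "UTC") + (0:99) * 600,
    x = 0, y = 0,
    h_accuracy = c(rep(5, 96), 31, 31, 30, NA))
  tr <- new_trajectory(fixes)
  out <- filter_fixes(tr, burn_in_days = 0)
  expect_equal(nrow(out$fixes), 98)            # the two 31 m fixes dropped
  expect_true(30 %in% out$fixes$h_accuracy)    # exactly 30 m retained
  expect_true(any(is.na(out$fixes$h_accuracy)))
  expect_equal(attr(out, "removed")[["accuracy"]], 2)
})

test_that("burn-in removes the first whole days from deployment start", {
  dec1 <- as.POSIXct("2021-12-01 00:00", tz = "UTC")
  fixes <- data.frame(animal_id = "a",
                      t_utc = c(as.POSIXct("2021-12-02 06:00", tz = "UTC"),
                                as.POSIXct("2021-12-07 06:00", tz = "UTC")),
                      x = 0, y = 0, h_accuracy = 5)
  tr <- new_trajectory(fixes, deploy_start = dec1)
  out <- filter_fixes(tr, burn_in_days = 5)
  expect_equal(nrow(out$fixes), 1)
  expect_equal(format(out$fixes$t_utc, "%d"), "07")
  # removing everything warns but returns an (empty) trajectory
  expect_warning(none <- filter_fixes(tr, burn_in_days = 40), "all fixes removed")
  expect_equal(nrow(none$fixes), 0)
})

test_that("filtering is idempotent", {
  set.seed(1)
  fixes <- data.frame(
    animal_id = "a",
    t_utc = as.POSIXct("2022-01-01 00:00", tz = "UTC") + (0:199) * 7200,
    x = 0, y = 0, h_accuracy = runif(200, 0, 60))
  tr <- new_trajectory(fixes)
  once <- filter_fixes(tr)
  twice <- filter_fixes(once)
  expect_equal(twice$fixes, once$fixes)
})

test_that("local-time conversion is DST-aware for Europe/Dublin", {
  fmt <- function(t) format(to_local_time(t, "Europe/Dublin"), "%H:%M")
  expect_equal(fmt(as.POSIXct("2022-01-15 05:00", tz = "UTC")), "05:00")
  expect_equal(fmt(as.POSIXct("2022-04-15 05:00", tz = "UTC")), "06:00")
  # the 2022 spring transition happened at 01:00 UTC on 27 March
  expect_equal(fmt(as.POSIXct("2022-03-27 00:30", tz = "UTC")), "00:30")
  expect_equal(fmt(as.POSIXct("2022-03-27 01:30", tz = "UTC")), "02:30")
  expect_error(to_local_time(Sys.time(), "Europe/Nowhere"), "unknown time zone")
})

test_that("steps: counts, lengths, degenerate flags and t_event anchoring", {
  xy <- rbind(c(0, 0), c(3, 4), c(3, 4), c(6, 8))
  st <- path_steps(xy)
  expect_equal(nrow(st), 3)
  expect_equal(st$length_m, c(5, 0, 5))
  expect_equal(st$degenerate, c(FALSE, TRUE, FALSE))
  expect_equal(st$t_event[1], as.POSIXct("2022-04-10 06:00:00", tz = "UTC"),
               ignore_attr = "tzone")
  expect_equal(st$duration_s, rep(600, 3))
  # fewer than 2 fixes -> no steps
  one <- new_trajectory(data.frame(animal_id = "a",
                                   t_utc = as.POSIXct("2022-01-01", tz = "UTC"),
                                   x = 0, y = 0))
  expect_equal(nrow(build_steps(one)), 0)
})

test_that("total step length is invariant under rigid motions", {
  set.seed(4)
  xy <- cbind(cumsum(rnorm(50)), cumsum(rnorm(50)))
  base <- sum(path_steps(xy)$length_m)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- xy %*% t(R)
  moved <- cbind(moved[, 1] + 123, moved[, 2] - 456)
  expect_equal(sum(path_steps(moved)$length_m), base)
})

test_that("planar projection agrees with geodesic distances and round-trips", {
  skip_if_not_installed("geosphere")
  p <- make_projection(-6.25, 53.43)
  lon <- c(-6.25, -6.20, -6.30, -6.22)
  lat <- c(53.43, 53.46, 53.40, 53.47)
  xy <- project_lonlat(lon, lat, p)
  for (i in 2:4) {
    d_tm <- sqrt((xy$x[i] - xy$x[1])^2 + (xy$y[i] - xy$y[1])^2)
    d_geo <- geosphere::distGeo(c(lon[1], lat[1]), c(lon[i], lat[i]))
    expect_lt(abs(d_tm - d_geo), 0.05)  # < 5 cm over ~5 km
  }
  rt <- unproject_xy(xy$x, xy$y, p)
  expect_equal(rt$lon, lon, tolerance = 1e-9)
  expect_equal(rt$lat, lat, tolerance = 1e-9)
})
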