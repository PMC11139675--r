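test_that("daily distance sums step lengths by local day and zero-fills", {
  t0 <- as.POSIXct("2022-04-10 10:00:00", tz = "UTC")
  fixes <- data.frame(
    animal_id = "a",
    t_utc = c(t0, t0 + 3600, t0 + 2 * 86400, t0 + 2 * 86400 + 3600),
    x = c(0, 5000, 0, 3000), y = c(0, 0, 0, 4000))
  st <- build_steps(new_trajectory(fixes))
  dd <- daily_distance(st)
  expect_equal(nrow(dd), 3)                       # includes empty middle day
  # two 5 km steps anchor to day 1 (incl. the multi-day gap step), one to day 3
  expect_equal(dd$distance_km, c(10, 0, 5))
  expect_equal(sum(dd$distance_km), sum(st$length_m) / 1000)
})

test_that("hand-built trajectory reproduces known per-day totals exactly", {
  t0 <- as.POSIXct("2022-05-01 00:00:00", tz = "UTC")
  # day 1: 3 + 4 km, day 2: 7 km; steps anchored to their earlier fix
  fixes <- data.frame(
    animal_id = "a",
    t_utc = t0 + c(3600, 7200, 10800, 90000, 93600),
    x = c(0, 3000, 3000, 3000, 10000), y = c(0, 0, 4000, 4000, 4000))
  dd <- daily_distance(build_steps(new_trajectory(fixes)))
  expect_equal(dd$distance_km, c(7, 7))
})

test_that("monthly cumulative keeps only fully-covered months unless exempted", {
  days <- seq(as.Date("2022-01-01"), as.Date("2022-03-15"), by = "day")
  daily <- data.frame(animal_id = "a", date = days, distance_km = 1)
  mc <- monthly_cumulative(daily)
  expect_setequal(mc$per_animal$month, c("2022-01", "2022-02"))
  expect_equal(mc$per_animal$distance_km[mc$per_animal$month == "2022-01"], 31)
  # exemption keeps the partial month
  mc2 <- monthly_cumulative(daily, keep_partial = "2022-03")
  expect_true("2022-03" %in% mc2$per_animal$month)
  # collective totals are additive across animals
  two <- rbind(daily, transform(daily, animal_id = "b"))
  mc3 <- monthly_cumulative(two)
  expect_equal(mc3$collective$distance_km[mc3$collective$month == "2022-02"], 56)
})

test_that("month-wise rank test flags shifted months and honours exclusions", {
  set.seed(8)
  mk <- function(month, mu, n = 60) {
    data.frame(animal_id = "a",
               date = as.Date(sprintf("2022-%02d-01", month)) + seq_len(n) %% 28,
               distance_km = rnorm(n, mu, 2))
  }
  # identical distributions: H small, adjusted p large
  same <- rbind(mk(1, 3), mk(2, 3), mk(3, 3))
  res <- monthly_distance_test(same)
  expect_gt(res$kw$p, 0.05)
  # a 2 km shift at n = 60/month is caught in >= 90% of replicates
  hits <- replicate(100, {
    d <- rbind(mk(1, 3), mk(2, 5))
    any(monthly_distance_test(d)$dunn$p_adjusted < 0.05)
  })
  expect_gte(mean(hits), 0.9)
  # excluded month vanishes from the report
  three <- rbind(mk(1, 3), mk(2, 3), mk(7, 10))
  res3 <- monthly_distance_test(three, exclude_months = 7)
  expect_false(any(grepl("2022-07", c(res3$dunn$group1, res3$dunn$group2))))
  expect_error(monthly_distance_test(mk(1, 3)), "at least 2 month")
})

test_that("rank test p-values are uniform under label permutation", {
  set.seed(12)
  x <- rnorm(60)
  p <- replicate(200, {
    g <- sample(rep(1:3, each = 20))
    kruskal_wallis(split(x, g))$p
  })
  expect_lt(suppressWarnings(ks.test(p, "punif"))$statistic, 0.15)
})

test_that("step-length summary pools, stratifies and flags degenerate cases", {
  st <- data.frame(animal_id = c("a", "a", "a", "b"),
                   length_m = c(3, 4, 5, 10),
                   duration_s = c(600, 600, 7200, 600))
  s <- step_length_summary(st, max_duration_min = 20)
  expect_equal(s$pooled$mean_m, mean(c(3, 4, 10)))  # 2 h step excluded
  sall <- step_length_summary(st, max_duration_min = NULL)
  expect_equal(sall$pooled$mean_m, mean(c(3, 4, 5, 10)))
  expect_equal(sall$per_animal$mean_m[sall$per_animal$animal_id == "a"], 4)
  single <- step_length_summary(st[4, ], max_duration_min = NULL)
  expect_true(single$pooled$degenerate)
  expect_equal(single$pooled$sd_m, 0)
})

test_that("simulated step displacements match the analytic Rayleigh mean", {
  # steps drawn from a Rayleigh(sigma) displacement model: E[L] = sigma*sqrt(pi/2)
  set.seed(13)
  sigma <- 40
  n <- 10000
  L <- sigma * sqrt(-2 * log(runif(n)))
  st <- data.frame(animal_id = "a", length_m = L, duration_s = 600)
  s <- step_length_summary(st)
  expect_equal(s$pooled$mean_m, sigma * sqrt(pi / 2),
               tolerance = 0.05)
})
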