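test_that("simple-average degree days match hand arithmetic and clamp at zero", {
  expect_equal(dd_tavg(8, 18, 10), 3)
  expect_equal(dd_tavg(0, 8, 10), 0)   # mean below base
  expect_equal(dd_tavg(10, 20, 10), 5) # base at tmin
  expect_error(dd_tavg(18, 8, 10), "tmax < tmin")
})

test_that("single-sine degree days reduce correctly at the branch boundaries", {
  expect_equal(dd_allen(10, 20, 10), 5)  # base = tmin: same as simple average
  expect_equal(dd_allen(8, 18, 18), 0)   # base = tmax
  # frozen value from the numeric midpoint-rule oracle (see helper)
  expect_equal(dd_allen(8, 18, 10), 3.3877378, tolerance = 1e-6)
  expect_equal(dd_allen(8, 18, 10), allen_numeric(8, 18, 10), tolerance = 1e-6)
  # constant-temperature day
  expect_equal(dd_allen(15, 15, 10), 5)
  expect_equal(dd_allen(15, 15, 20), 0)
})

test_that("single-sine closed form agrees with numeric integration and dominates tavg", {
  set.seed(42)
  n <- 500
  tmin <- runif(n, -5, 25)
  tmax <- tmin + runif(n, 0, 15)
  base <- runif(n, 0, 30)
  closed <- dd_allen(tmin, tmax, base)
  oracle <- mapply(allen_numeric, tmin, tmax, base)
  expect_lt(max(abs(closed - oracle)), 1e-6)
  # Jensen: the sine average of a convex clamp dominates the clamp of the mean
  expect_true(all(closed >= dd_tavg(tmin, tmax, base) - 1e-12))
  # both methods non-increasing in base temperature
  expect_true(all(dd_allen(tmin, tmax, base + 1) <= closed + 1e-12))
  expect_true(all(dd_tavg(tmin, tmax, base + 1) <=
                    dd_tavg(tmin, tmax, base) + 1e-12))
})

test_that("closed-form branches are continuous at base = tmin and base = tmax", {
  h <- 1e-10
  for (tt in list(c(3, 17), c(-2, 9), c(10, 10.5))) {
    expect_lt(abs(dd_allen(tt[1], tt[2], tt[1] + h) -
                    dd_allen(tt[1], tt[2], tt[1] - h)), 1e-9)
    expect_lt(abs(dd_allen(tt[1], tt[2], tt[2] + h) -
                    dd_allen(tt[1], tt[2], tt[2] - h)), 1e-9)
  }
})

test_that("accumulation runs from January 1 and matches day-by-day sums", {
  w <- data.frame(location_id = "a", date = as.Date("2020-01-01") + 0:2,
                  tmin = 8, tmax = 18, source = "station")
  g <- accumulate_gdd(w, base_temp = 10, method = "tavg")
  expect_equal(g$cum_gdd, c(3, 6, 9))
  expect_equal(g$doy, 1:3)

  set.seed(7)
  w5 <- data.frame(location_id = "b", date = as.Date("2021-01-01") + 0:4,
                   tmin = rnorm(5, 8, 3), source = "station")
  w5$tmax <- w5$tmin + runif(5, 2, 12)
  g5 <- accumulate_gdd(w5, base_temp = 10, method = "allen")
  expect_equal(g5$cum_gdd, cumsum(dd_allen(w5$tmin, w5$tmax, 10)))

  # base below every tmin: allen and tavg accumulate identically
  g_a <- accumulate_gdd(w5, base_temp = 0, method = "allen")
  g_t <- accumulate_gdd(w5, base_temp = 0, method = "tavg")
  expect_equal(g_a$cum_gdd, g_t$cum_gdd)
})

test_that("cumulative GDD is non-decreasing and non-increasing in base temperature", {
  w <- generate_weather(tiny_world_config())
  for (m in c("tavg", "allen")) {
    g <- accumulate_gdd(w, 10, m)
    by_grp <- split(g$cum_gdd, paste(g$location_id, format(g$date, "%Y")))
    expect_true(all(vapply(by_grp, function(x) all(diff(x) >= 0), TRUE)))
  }
  g5 <- accumulate_gdd(w, 5, "allen")
  g9 <- accumulate_gdd(w, 9, "allen")
  expect_true(all(g9$cum_gdd <= g5$cum_gdd + 1e-12))
})

test_that("leap years reach day-of-year 366", {
  w <- data.frame(location_id = "a",
                  date = seq(as.Date("2008-01-01"), as.Date("2008-12-31"), "day"),
                  tmin = 5, tmax = 15, source = "station")
  g <- accumulate_gdd(w, 10, "tavg")
  expect_equal(nrow(g), 366)
  expect_equal(max(g$doy), 366)
})

test_that("weather validation rejects broken inputs with addressed errors", {
  w <- data.frame(location_id = "a", date = as.Date("2020-01-01") + 0:2,
                  tmin = 8, tmax = 18, source = "station")
  w_bad <- w; w_bad$tmax[2] <- 0
  expect_error(accumulate_gdd(w_bad, 10), "tmax < tmin.*'a' on 2020-01-02")
  w_gap <- w[-2, ]
  expect_error(accumulate_gdd(w_gap, 10), "gap.*2020-01-02",
               class = "thermophen_missing_coverage")
  w_late <- w; w_late$date <- w_late$date + 30  # does not start Jan 1
  expect_error(accumulate_gdd(w_late, 10), class = "thermophen_missing_coverage")
  expect_error(accumulate_gdd(w[c(1, 1, 2, 3), ], 10), "duplicate")
  expect_error(accumulate_gdd(w, base_temp = 50), "base_temp")
  w_src <- w; w_src$source <- "satellite"
  expect_error(accumulate_gdd(w_src, 10), "unknown weather source")
})

test_that("gdd_at looks up exact values and rejects uncovered dates", {
  w <- data.frame(location_id = "a", date = as.Date("2020-01-01") + 0:2,
                  tmin = 8, tmax = 18, source = "station")
  g <- accumulate_gdd(w, 10, "tavg")
  expect_equal(gdd_at(g, "a", as.Date("2020-01-03")), 9)
  expect_equal(gdd_at(g, "a", as.Date("2020-01-01")), g$daily_dd[1])
  expect_error(gdd_at(g, "a", as.Date("2019-12-31")),
               class = "thermophen_missing_coverage")
  expect_error(gdd_at(g, "zz", as.Date("2020-01-02")),
               class = "thermophen_missing_coverage")
})
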