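test_that("solar elevation matches equinox geometry at the equator", {
  noon <- as.POSIXct("2000-03-20 12:07:00", tz = "UTC")
  expect_gt(solar_elevation(0, 0, noon), 85)
  expect_lt(solar_elevation(0, 0, noon - 12 * 3600), -85)
  # hour-angle rate: ~15 degrees per hour away from local solar noon
  for (h in 1:5) {
    e <- solar_elevation(0, 0, noon + h * 3600)
    expect_lt(abs((90 - e) - 15 * h), 2)
  }
  # 22:00 local solar time -> about 60 degrees below the horizon
  expect_lt(abs(solar_elevation(0, 0, noon + 10 * 3600) - (-60)), 2)
})

test_that("solar elevation stays in [-90, 90] everywhere", {
  set.seed(42)
  lat <- runif(200, -90, 90); lon <- runif(200, -180, 180)
  t0 <- as.POSIXct("1990-01-01", tz = "UTC") +
    runif(200, 0, 36 * 365.25 * 86400)
  e <- solar_elevation(lat, lon, t0)
  expect_true(all(e >= -90 & e <= 90))
  expect_error(solar_elevation(91, 0, t0[1]), "latitude")
  expect_error(solar_elevation(0, 181, t0[1]), "longitude")
})

test_that("nocturnality threshold is strict and configurable", {
  rec <- data.frame(lat = 0, lon = 0,
                    timestamp = as.POSIXct("2010-07-10 17:30:00", tz = "UTC"))
  e <- solar_elevation(rec$lat, rec$lon, rec$timestamp)
  expect_false(classify_nocturnal(rec, threshold_deg = e))        # boundary
  expect_false(classify_nocturnal(rec, threshold_deg = e - 0.1))  # elev above
  expect_true(classify_nocturnal(rec, threshold_deg = e + 0.1))   # elev below
})

test_that("classification agrees with a minute-table twilight oracle", {
  # For random site/date pairs, tabulate the sun minute by minute and read
  # off the civil-dark minutes; classify_nocturnal at those instants must
  # agree everywhere (identical geometry, independent bookkeeping).
  set.seed(7)
  for (i in 1:6) {
    lat <- runif(1, -35, 35); lon <- runif(1, -40, 60)
    day <- as.POSIXct("2012-01-01", tz = "UTC") +
      sample.int(365, 1) * 86400
    mins <- day + seq(0, 86340, by = 600)
    elev <- solar_elevation(lat, lon, mins)
    table_dark <- elev < -6
    rec <- data.frame(lat = lat, lon = lon, timestamp = mins)
    expect_identical(classify_nocturnal(rec), table_dark)
  }
})

test_that("nocturnal proportion counts only active records", {
  act <- rep(c(TRUE, FALSE), c(50, 30))
  noc <- c(rep(c(TRUE, FALSE), c(25, 25)), rep(TRUE, 30))
  res <- nocturnal_proportion(act, noc)
  expect_equal(res$p, 0.5)
  expect_equal(res$n, 50)
  expect_equal(nocturnal_proportion(rep(TRUE, 4), rep(TRUE, 4))$p, 1.0)
  expect_error(nocturnal_proportion(rep(FALSE, 5), rep(TRUE, 5)), "active")
})

make_track <- function(lons, lats, hours, start = "2015-06-01") {
  data.frame(lon = lons, lat = lats,
             timestamp = as.POSIXct(start, tz = "UTC") + hours * 3600,
             method = "gps")
}

test_that("cluster rule: spread fixes stay active, tight bouts cluster", {
  # 5 fixes pairwise > 200 m apart
  tr <- make_track(30 + (0:4) * 0.01, rep(-2, 5), 0:4)
  res <- detect_clusters(tr)
  expect_equal(res$cluster, rep(0L, 5))
  expect_true(all(res$active))

  # 4 fixes within 50 m over 6 h -> one cluster of exactly those 4
  jit <- c(0, 1, -1, 0.5) * 2e-4   # ~22 m spacing
  tr <- make_track(30 + jit, -2 + rev(jit) / 2, c(0, 2, 4, 6))
  res <- detect_clusters(tr)
  expect_equal(res$cluster, rep(1L, 4))
  expect_equal(res$clusters$n, 4L)
  expect_false(any(res$active))

  # 3 co-located fixes with > 2-day gaps between consecutive fixes
  tr <- make_track(rep(30, 3), rep(-2, 3), c(0, 49, 98))
  res <- detect_clusters(tr)
  expect_equal(res$cluster, rep(0L, 3))

  # two bouts separated by 5 days are never merged
  tr <- rbind(make_track(rep(30, 3), rep(-2, 3), c(0, 1, 2)),
              make_track(rep(30, 3), rep(-2, 3), c(120, 121, 122)))
  res <- detect_clusters(tr)
  expect_equal(unique(res$cluster), c(1L, 2L))
})

test_that("min_fixes reads 'more than 2' strictly", {
  tr <- make_track(rep(30, 2), rep(-2, 2), c(0, 1))
  expect_equal(detect_clusters(tr)$cluster, c(0L, 0L))
  tr3 <- make_track(rep(30, 3), rep(-2, 3), c(0, 1, 2))
  expect_equal(detect_clusters(tr3)$cluster, rep(1L, 3))
})

test_that("cluster labels are invariant under rigid translation", {
  set.seed(11)
  tr <- simulate_gps_track(6, 8, 1,
                           rest_bouts = data.frame(start = c(5, 30),
                                                   n_fixes = c(4, 5),
                                                   jitter_m = c(20, 40)),
                           seed = 3)
  base <- detect_clusters(tr)$cluster
  tr2 <- tr; tr2$lon <- tr2$lon + 5; tr2$lat <- tr2$lat + 3
  expect_identical(detect_clusters(tr2)$cluster, base)
})

test_that("shrinking radius or window never grows the clustered set", {
  tr <- simulate_gps_track(8, 8, 0.5,
                           rest_bouts = data.frame(start = c(3, 25, 50),
                                                   n_fixes = c(5, 3, 6),
                                                   jitter_m = c(45, 10, 30)),
                           seed = 9)
  n_clustered <- function(radius_m, window_days)
    sum(detect_clusters(tr, radius_m, window_days)$cluster > 0)
  full <- n_clustered(100, 2)
  expect_lte(n_clustered(50, 2), full)
  expect_lte(n_clustered(100, 0.5), full)
  expect_lte(n_clustered(25, 0.25), full)
})

test_that("unordered timestamps are rejected", {
  tr <- make_track(rep(30, 3), rep(-2, 3), c(0, 2, 1))
  expect_error(detect_clusters(tr), "increasing")
})
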