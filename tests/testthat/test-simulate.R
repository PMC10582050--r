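test_that("meta dataset generator is deterministic and honors contracts", {
  a <- simulate_meta_dataset(20, -0.3, 0.15, c(hfi = -0.5), seed = 5)
  b <- simulate_meta_dataset(20, -0.3, 0.15, c(hfi = -0.5), seed = 5)
  expect_identical(a, b)
  c_ <- simulate_meta_dataset(20, -0.3, 0.15, c(hfi = -0.5), seed = 6)
  expect_false(identical(a$effects$estimate, c_$effects$estimate))
  expect_error(simulate_meta_dataset(1, 0, 0.1), "k")
  expect_error(simulate_meta_dataset(10, 0, -0.1), "tau2")
})

test_that("degenerate variances collapse observed effects onto the mean", {
  d <- simulate_meta_dataset(50, -0.4, 0, v_median = 1e-12, seed = 1)
  expect_true(all(abs(d$effects$estimate - (-0.4)) < 1e-5))
  expect_equal(d$truth$site_effects, rep(-0.4, 50))
})

test_that("site observation generator plants proportions and counts", {
  sp <- list(p_low = 0.4, p_high = 0.5, n_units = 40, mean_fixes = 25,
             dispersion = 8, d_target = -0.5)
  a <- simulate_site_observations(sp, seed = 3)
  expect_identical(a, simulate_site_observations(sp, seed = 3))
  expect_equal(nrow(a$units), 80)
  expect_setequal(unique(a$observations$method), "camera")
  # planted nocturnality proportions recovered from the truth flags
  ob <- merge(a$observations, a$units[, c("unit_id", "group")])
  p_lo <- mean(ob$truth_nocturnal[ob$group == "low"])
  n_lo <- sum(ob$group == "low")
  expect_lt(abs(p_lo - 0.4), 3 * sqrt(0.4 * 0.6 / n_lo))
  # disturbance values separate the groups at the median
  expect_true(all(a$units$disturbance_value[a$units$group == "low"] < 1))
  expect_true(all(a$units$disturbance_value[a$units$group == "high"] > 1))
  expect_error(simulate_site_observations(
    modifyList(sp, list(p_low = 0)), seed = 1), "proportions")
  expect_error(simulate_site_observations(
    modifyList(sp, list(n_units = 1)), seed = 1), "units")
})

test_that("timestamps planted for night/day classify accordingly", {
  sp <- list(p_low = 0.4, p_high = 0.5, n_units = 10, mean_fixes = 10,
             dispersion = 5, d_target = -0.3)
  a <- simulate_site_observations(sp, seed = 8)
  noc <- classify_nocturnal(a$observations)
  expect_identical(noc, a$observations$truth_nocturnal)
})

test_that("planted Hedges' d is recovered within Monte-Carlo error", {
  sp <- list(p_low = 0.4, p_high = 0.5, n_units = 100, mean_fixes = 25,
             dispersion = 8, d_target = -0.5)
  ds <- sapply(1:30, function(s) {
    a <- simulate_site_observations(sp, seed = s)
    cnt <- table(factor(a$observations$unit_id, levels = a$units$unit_id))
    lo <- as.numeric(cnt[a$units$group == "low"])
    hi <- as.numeric(cnt[a$units$group == "high"])
    hedges_d(mean(lo), sd(lo), length(lo), mean(hi), sd(hi),
             length(hi))$estimate
  })
  se <- sd(ds) / sqrt(length(ds))
  expect_lt(abs(mean(ds) - (-0.5)), 3 * se + 0.02)  # small solver bias bound
})

test_that("gps track generator respects its geometry contracts", {
  bouts <- data.frame(start = c(10, 30), n_fixes = c(4, 5),
                      jitter_m = c(30, 45))
  tr <- simulate_gps_track(6, 8, 1, bouts, seed = 12)
  expect_identical(tr, simulate_gps_track(6, 8, 1, bouts, seed = 12))
  in_bout <- tr$truth_resting
  # travel fixes: consecutive pairs outside bouts separated by > 200 m
  steps <- gc_distance_km(tr$lon[-nrow(tr)], tr$lat[-nrow(tr)],
                          tr$lon[-1], tr$lat[-1]) * 1000
  outside <- !(in_bout[-nrow(tr)] | in_bout[-1])
  expect_true(all(steps[outside] > 200))
  # bout fixes: within 50 m of their anchor
  for (b in 1:2) {
    idx <- bouts$start[b] + seq_len(bouts$n_fixes[b]) - 1
    d <- gc_distance_km(tr$lon[idx[1]], tr$lat[idx[1]],
                        tr$lon[idx], tr$lat[idx]) * 1000
    expect_true(all(d < 50))
  }
  expect_error(simulate_gps_track(5, 8, 1,
                                  data.frame(start = 1, n_fixes = 3,
                                             jitter_m = 150)), "jitter")
  expect_error(simulate_gps_track(5, 8, 1,
                                  data.frame(start = 1, n_fixes = 2,
                                             jitter_m = 10)), "fixes")
})

test_that("cluster detector recovers exactly the planted bouts", {
  # no bouts -> no clusters
  tr0 <- simulate_gps_track(5, 8, 1, NULL, seed = 2)
  expect_equal(sum(detect_clusters(tr0)$cluster), 0)
  # one bout of 4 fixes over ~12 h -> exactly one cluster of those 4
  b1 <- data.frame(start = 15, n_fixes = 4, jitter_m = 25)
  tr1 <- simulate_gps_track(6, 8, 1, b1, seed = 4)
  res1 <- detect_clusters(tr1)
  expect_equal(nrow(res1$clusters), 1)
  expect_identical(res1$cluster > 0, tr1$truth_resting)
  # two bouts separated by 5 days -> two clusters, never merged
  b2 <- data.frame(start = c(5, 45), n_fixes = c(4, 4), jitter_m = c(20, 20))
  tr2 <- simulate_gps_track(7, 8, 1, b2, seed = 6)
  res2 <- detect_clusters(tr2)
  expect_equal(nrow(res2$clusters), 2)
  expect_identical(res2$cluster > 0, tr2$truth_resting)
  # cluster members end within the radius of the final centroid
  for (k in 1:2) {
    mem <- which(res2$cluster == k)
    d <- gc_distance_km(res2$clusters$centroid_lon[k],
                        res2$clusters$centroid_lat[k],
                        tr2$lon[mem], tr2$lat[mem]) * 1000
    expect_true(all(d <= 100))
  }
})

test_that("NDVI stack generator hits its calibration targets", {
  st <- simulate_ndvi_stack(12, c(6, 6),
                            0.5 + 0.2 * sin(2 * pi * (1:12) / 12),
                            target_spatial_cv = 0.2,
                            target_temporal_cv = 0.15, seed = 7)
  expect_identical(st, simulate_ndvi_stack(
    12, c(6, 6), 0.5 + 0.2 * sin(2 * pi * (1:12) / 12),
    target_spatial_cv = 0.2, target_temporal_cv = 0.15, seed = 7))
  nd <- ndvi_metrics(st, c(30.03, -1.97), 500)
  expect_lt(abs(nd$ndvi_a - 0.5) / 0.5, 0.05)
  expect_lt(abs(nd$ndvi_sp - 0.2) / 0.2, 0.10)
  expect_lt(abs(nd$ndvi_tm - 0.15) / 0.15, 0.10)
  expect_true(all(sapply(st$grids, function(g) all(abs(g$values) <= 1))))

  # zero-variation config degenerates to a constant stack
  stc <- simulate_ndvi_stack(3, c(2, 2), 0.4, 0, 0, seed = 1)
  expect_true(all(sapply(stc$grids, function(g) all(g$values == 0.4))))
  expect_error(simulate_ndvi_stack(3, c(2, 2), 0.4, 5, 0, seed = 1),
               "outside")
  expect_error(simulate_ndvi_stack(3, c(2, 2), 0.4, 0.1, 0.2, seed = 1),
               "constant mean_curve")
  expect_error(simulate_ndvi_stack(1, c(2, 2), 0.4), "months")
})
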