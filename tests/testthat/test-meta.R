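test_that("degenerate fits recover exact answers", {
  f <- fit_ml_meta(c(0.5, 0.5, 0.5), c(0.2, 0.2, 0.2))
  expect_equal(f$beta$estimate[1], 0.5)
  expect_equal(f$tau2, 0)
  # equal variances, tau2 = 0 -> intercept is the arithmetic mean
  y <- c(0.1, 0.1, 0.12, 0.08)
  f2 <- fit_ml_meta(y, rep(0.5, 4))
  expect_equal(f2$beta$estimate[1], mean(y), tolerance = 1e-6)
})

test_that("adding a constant shifts the intercept and nothing else", {
  set.seed(21)
  y <- rnorm(15, -0.3, 0.4); v <- runif(15, 0.02, 0.2)
  a <- fit_ml_meta(y, v)
  b <- fit_ml_meta(y + 1.7, v)
  expect_equal(b$beta$estimate[1], a$beta$estimate[1] + 1.7, tolerance = 1e-6)
  expect_equal(b$tau2, a$tau2, tolerance = 1e-8)
  expect_equal(b$beta$se, a$beta$se, tolerance = 1e-8)
})

test_that("profiled ML matches the grid-search oracle on random instances", {
  set.seed(33)
  for (i in 1:30) {
    k <- sample(5:30, 1)
    tau2 <- runif(1, 0, 0.5)
    v <- runif(k, 0.02, 0.3)
    with_mod <- i %% 2 == 0
    x <- if (with_mod) rnorm(k)
    y <- -0.3 + (if (with_mod) 0.4 * x else 0) + rnorm(k, 0, sqrt(tau2 + v))
    X <- if (with_mod) cbind(1, x) else NULL
    fit <- fit_ml_meta(y, v, X)
    oracle <- oracle_grid_loglik(y, v, if (with_mod) x else NULL)
    expect_gte(fit$logLik, oracle$logLik - 1e-10)  # never worse than grid
    expect_lt(abs(fit$logLik - oracle$logLik), 1e-3)
  }
})

test_that("fit agrees with reference software (metafor, ML)", {
  set.seed(44)
  for (i in 1:10) {
    k <- sample(10:30, 1)
    x <- rnorm(k); v <- runif(k, 0.02, 0.2)
    y <- -0.2 - 0.5 * x + rnorm(k, 0, sqrt(0.1 + v))
    fit <- fit_ml_meta(y, v, cbind(intercept = 1, x = x))
    ref <- metafor::rma(y, v, mods = ~x, method = "ML")
    expect_equal(fit$beta$estimate, as.numeric(ref$beta), tolerance = 1e-5)
    expect_equal(fit$tau2, ref$tau2, tolerance = 1e-4)
    expect_equal(fit$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
    expect_equal(aicc(fit), metafor::fitstats(ref)["AICc:", 1],
                 tolerance = 1e-5, ignore_attr = TRUE)
    q <- qe_test(fit)
    expect_equal(q$qe, ref$QE, tolerance = 1e-8)
    expect_equal(q$df, ref$k - ref$p)
  }
})

test_that("input contracts are enforced", {
  expect_error(fit_ml_meta(c(0.1, 0.2), c(0.1, -0.1)), "variances")
  expect_error(fit_ml_meta(c(0.1, 0.2), c(0.1, 0.1),
                           cbind(1, c(2, 2))), "rank")
  expect_error(fit_ml_meta(c(0.1), c(0.1)), "more effect sizes")
})

test_that("heterogeneity statistics follow their closed forms", {
  # equal weights: s2 equals the common variance exactly
  y <- c(-0.8, -0.2, 0.1, 0.4, -0.6)
  f <- fit_ml_meta(y, rep(0.1, 5))
  h <- heterogeneity(f)
  expect_equal(h$s2, 0.1)
  expect_equal(h$i2, 100 * f$tau2 / (f$tau2 + 0.1))
  expect_true(h$tau2_ci[1] <= f$tau2 + 1e-10 && f$tau2 <= h$tau2_ci[2])
  # tau2 = 0 -> I2 = 0
  f0 <- fit_ml_meta(rep(0.3, 5), rep(0.1, 5))
  expect_equal(heterogeneity(f0)$i2, 0)
})

test_that("Q-profile bounds invert the generalized Q statistic", {
  set.seed(55)
  y <- rnorm(12, -0.3, 0.5); v <- runif(12, 0.02, 0.1)
  f <- fit_ml_meta(y, v)
  h <- heterogeneity(f)
  qg <- function(t2) carnmeta:::.q_gen(t2, y, f$X, v)
  df <- 11
  if (h$tau2_ci[1] > 0)
    expect_lt(abs(qg(h$tau2_ci[1]) - qchisq(0.975, df)), 1e-6)
  expect_lt(abs(qg(h$tau2_ci[2]) - qchisq(0.025, df)), 1e-6)
})

test_that("heterogeneity CIs agree with metafor for intercept-only models", {
  set.seed(66)
  y <- rnorm(20, -0.25, 0.45); v <- runif(20, 0.02, 0.15)
  f <- fit_ml_meta(y, v)
  h <- heterogeneity(f)
  ref <- metafor::rma(y, v, method = "ML")
  ci <- metafor::confint.rma.uni(ref)
  # metafor inverts Q with a ~1e-4 root tolerance; agree to that precision
  expect_equal(h$tau2_ci[1], ci$random["tau^2", "ci.lb"], tolerance = 1e-3)
  expect_equal(h$tau2_ci[2], ci$random["tau^2", "ci.ub"], tolerance = 1e-3)
  expect_equal(h$i2, ref$I2, tolerance = 1e-6)
  expect_equal(h$i2_ci[1], ci$random["I^2(%)", "ci.lb"], tolerance = 1e-3)
  expect_equal(h$i2_ci[2], ci$random["I^2(%)", "ci.ub"], tolerance = 1e-3)
})

test_that("QE has the hand-computed value on a tiny instance", {
  f <- fit_ml_meta(c(0, 1, 2), c(1, 1, 1))
  q <- qe_test(f)
  expect_equal(q$qe, 2); expect_equal(q$df, 2)
  # on-the-line effects: QE = 0, p = 1
  f0 <- fit_ml_meta(rep(0.4, 4), rep(0.3, 4))
  q0 <- qe_test(f0)
  expect_equal(q0$qe, 0); expect_equal(q0$p, 1)
})

test_that("AICc exceeds AIC and matches its closed form", {
  set.seed(8)
  y <- rnorm(10, 0, 0.5); v <- runif(10, 0.05, 0.2)
  f <- fit_ml_meta(y, v)
  p <- f$p + 1
  aic <- -2 * f$logLik + 2 * p
  expect_equal(aicc(f), aic + 2 * p * (p + 1) / (f$k - p - 1))
  expect_gt(aicc(f), aic)
  f4 <- fit_ml_meta(y[1:4], v[1:4], cbind(1, rnorm(4)))
  expect_error(aicc(f4), "undefined")
})

test_that("all-subsets search counts models and normalizes weights", {
  set.seed(9)
  k <- 25
  cv <- as.data.frame(matrix(rnorm(k * 6), k, 6))
  names(cv) <- paste0("m", 1:6)
  y <- rnorm(k, -0.2, 0.4); v <- runif(k, 0.02, 0.1)
  res <- model_search(y, v, cv)
  expect_equal(nrow(res$table), 64)
  expect_equal(sum(res$table$weight), 1)
  expect_equal(res$table$delta_aicc[1], 0)
  expect_true(!is.unsorted(res$table$aicc))
  # one forbidden pair removes the 16 subsets containing both members
  res2 <- model_search(y, v, cv,
                       forbidden_pairs = rbind(c("m1", "m2")))
  expect_equal(nrow(res2$table), 48)
})

test_that("the search prefers the true moderator under strong signal", {
  set.seed(10)
  wins <- 0
  for (r in 1:40) {
    k <- 40
    cv <- data.frame(m1 = rnorm(k), m2 = rnorm(k))
    y <- -0.3 - 0.8 * cv$m1 + rnorm(k, 0, sqrt(0.02 + 0.05))
    v <- rep(0.05, k)
    res <- model_search(y, v, cv)
    if (res$table$moderators[1] == "m1") wins <- wins + 1
  }
  expect_gt(wins / 40, 0.7)
})

test_that("forest data carries per-site rows plus a pooled summary", {
  set.seed(13)
  ef <- data.frame(site_id = paste0("s", 1:8),
                   estimate = rnorm(8, -0.3, 0.5),
                   variance = runif(8, 0.02, 0.2))
  fd <- forest_data(ef)
  expect_equal(nrow(fd), 9)
  expect_true(fd$pooled[9])
  body <- fd[!fd$pooled, ]
  expect_true(!is.unsorted(-body$estimate))
  expect_equal(sum(body$weight), 1)
  expect_true(all(body$ci_lb < body$estimate & body$estimate < body$ci_ub))
})
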