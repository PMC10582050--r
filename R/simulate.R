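# Synthetic-data generators. The field gives no generative model (the method
# is a meta-analysis of published studies), so every distribution here is an
# artifact choice with recoverable ground truth; the methods vignette
# documents each one and what it does and does not emulate.

#' Simulate a meta-analytic dataset with known truth
#'
#' Per-site true effects follow the random-effects model
#' `theta_i = mu + x_i' beta + N(0, tau2)`; observed effects add sampling
#' noise `y_i = theta_i + N(0, v_i)` with lognormal sampling variances
#' (median `v_median`, log-scale SD 0.4 -- the magnitude range of published
#' per-site effect-size variances). Covariates are returned unscaled.
#'
#' @param k Number of sites (>= 2).
#' @param mu True mean effect.
#' @param tau2 True between-site variance (>= 0).
#' @param beta Named numeric vector of true moderator coefficients (possibly
#'   empty), on the scaled-moderator scale.
#' @param moderator_spec Named list of functions, each taking `k` and
#'   returning `k` raw covariate values. Defaults to standard-normal draws
#'   for every name in `beta`.
#' @param v_median Median sampling variance (default 0.05).
#' @param seed Integer seed; same inputs + seed give identical output.
#' @return List with `effects` (site_id, estimate, variance), `covariates`
#'   (site_id + raw moderators) and `truth` (`SyntheticTruth`: mu, tau2,
#'   beta, site_effects, seed).
#' @export
simulate_meta_dataset <- function(k, mu, tau2, beta = numeric(0),
                                  moderator_spec = NULL, v_median = 0.05,
                                  seed = 1) {
  if (k < 2) stop("invalid config: k must be >= 2")
  if (tau2 < 0) stop("invalid config: tau2 must be >= 0")
  if (length(beta) > 0 && is.null(names(beta)))
    names(beta) <- paste0("mod", seq_along(beta))
  withr::with_seed(seed, {
    raw <- lapply(names(beta), function(nm) {
      gen <- if (!is.null(moderator_spec[[nm]])) moderator_spec[[nm]]
             else function(k) stats::rnorm(k)
      gen(k)
    })
    names(raw) <- names(beta)
    Xs <- if (length(beta)) scale(do.call(cbind, raw)) else
      matrix(0, k, 0)
    theta <- mu + drop(Xs %*% beta) + stats::rnorm(k, 0, sqrt(tau2))
    vi <- stats::rlnorm(k, log(v_median), 0.4)
    yi <- theta + stats::rnorm(k, 0, sqrt(vi))
    site_id <- sprintf("site_%02d", seq_len(k))
    covs <- data.frame(site_id = site_id)
    for (nm in names(raw)) covs[[nm]] <- raw[[nm]]
    list(effects = data.frame(site_id = site_id, estimate = yi, variance = vi),
         covariates = covs,
         truth = list(mu = mu, tau2 = tau2, beta = beta,
                      site_effects = theta, seed = seed))
  })
}

# Group means hitting a Hedges' d target at the negative-binomial SD:
# solve mean_high - mean_low = d * pooled SD with the SD evaluated once at
# the base mean (second-order approximation; bias << Monte-Carlo error).
.nb_group_means <- function(base_mean, d_target, dispersion) {
  sd0 <- sqrt(base_mean + base_mean^2 / dispersion)
  delta <- d_target * sd0
  c(low = base_mean - delta / 2, high = base_mean + delta / 2)
}

#' Simulate one site's observations with planted effect sizes
#'
#' Builds two disturbance groups of sample units. Per-unit active-fix counts
#' are negative binomial (overdispersed, mimicking camera/GPS detection
#' intensity) with group means solved so the expected Hedges' d equals
#' `d_target`; each active observation is flagged nocturnal with probability
#' `p_low` or `p_high` by its unit's group, so the expected log response
#' ratio is `ln(p_low / p_high)`. Nocturnal observations are stamped at
#' 22:00 UTC and diurnal ones at 10:00 UTC at a site near the prime
#' meridian, so solar-elevation classification recovers the planted flags.
#'
#' @param site_params List with `p_low`, `p_high` (in (0,1)),
#'   `n_units` per group (>= 2), `mean_fixes` (per-unit NB mean),
#'   `dispersion` (NB size; Inf = Poisson), `d_target` (planted SMD) and
#'   optionally `site_id`, `lon`, `lat`.
#' @param seed Integer seed.
#' @return List with `observations` (ObservationRecord table: site_id,
#'   unit_id, timestamp, lon, lat, method, truth_nocturnal), `units`
#'   (unit_id, lon, lat, disturbance_value, group) and `truth`.
#' @export
simulate_site_observations <- function(site_params, seed = 1) {
  p <- site_params
  if (is.null(p$site_id)) p$site_id <- "site_01"
  if (is.null(p$lon)) p$lon <- 30
  if (is.null(p$lat)) p$lat <- -2
  if (p$n_units < 2) stop("invalid config: need >= 2 units per group")
  if (p$p_low <= 0 || p$p_low >= 1 || p$p_high <= 0 || p$p_high >= 1)
    stop("invalid config: nocturnality proportions must be inside (0,1)")
  if (!is.finite(p$dispersion) && abs(p$d_target) > 0 && p$mean_fixes == 0)
    stop("invalid config: zero within-group variance with nonzero d target")
  means <- .nb_group_means(p$mean_fixes, p$d_target, p$dispersion)
  if (means["low"] <= 0)
    stop("invalid config: d target too large for the base mean")

  withr::with_seed(seed, {
    n <- p$n_units
    units <- data.frame(
      unit_id = sprintf("%s_u%03d", p$site_id, seq_len(2 * n)),
      lon = p$lon + c(seq(-0.20, -0.01, length.out = n),
                      seq(0.01, 0.20, length.out = n)),
      lat = p$lat,
      disturbance_value = c(stats::runif(n, 0, 1), stats::runif(n, 1, 2)),
      group = rep(c("low", "high"), each = n))
    rnb <- function(m, mu_) {
      if (is.finite(p$dispersion)) stats::rnbinom(m, size = p$dispersion, mu = mu_)
      else stats::rpois(m, mu_)
    }
    counts <- ifelse(units$group == "low", rnb(2 * n, means["low"]),
                     rnb(2 * n, means["high"]))
    obs <- do.call(rbind, lapply(seq_len(2 * n), function(i) {
      m <- counts[i]
      if (m == 0) return(NULL)
      p_noc <- if (units$group[i] == "low") p$p_low else p$p_high
      noc <- stats::runif(m) < p_noc
      day <- sample.int(120, m, replace = TRUE)
      hour <- ifelse(noc, 22, 10)
      data.frame(site_id = p$site_id, unit_id = units$unit_id[i],
                 timestamp = as.POSIXct("2015-01-01", tz = "UTC") +
                   (day - 1) * 86400 + hour * 3600 + seq_len(m) - 1,
                 lon = units$lon[i], lat = units$lat[i],
                 method = "camera", truth_nocturnal = noc)
    }))
    list(observations = obs, units = units,
         truth = list(p_low = p$p_low, p_high = p$p_high,
                      d_target = p$d_target, group_means = means,
                      expected_rr = log(p$p_low / p$p_high), seed = seed))
  })
}

#' Synthetic per-site effect-size and covariate reference table
#'
#' Builds a complete per-site analysis table of the shape the meta-regression
#' stage consumes -- 30 spatial effects (Hedges' d scale) and 18 temporal
#' effects (log response ratio scale) on shared sites, with all six raw
#' site-level moderators -- from a known generative model. The vendored copy
#' under `inst/extdata/synthetic_site_effects.csv` is this function's output
#' at the default seed; it is a synthetic stand-in with documented ground
#' truth, not field data. Effect, variance and moderator magnitudes are
#' chosen to be realistic for carnivore disturbance-response syntheses.
#'
#' @param seed Integer seed (default 42).
#' @return Data.frame: `site_id`, `response`, `estimate`, `variance`, and
#'   the six raw moderators; attribute `truth` holds the generative
#'   parameters.
#' @export
simulate_reference_table <- function(seed = 42) {
  k <- 30; k_t <- 18
  mu_sp <- -0.25; tau2_sp <- 0.20
  beta_sp <- c(cat_a = 0, hfi_a = 0, hfi_sp = 0.15, ndvi_a = 0,
               ndvi_sp = -0.45, ndvi_tm = 0.10)
  mu_tm <- -0.07; tau2_tm <- 0.02
  beta_tm <- c(cat_a = -0.05, hfi_a = 0, hfi_sp = 0.03, ndvi_a = -0.01,
               ndvi_sp = -0.03, ndvi_tm = 0)
  withr::with_seed(seed, {
    covs <- data.frame(
      site_id = sprintf("site_%02d", seq_len(k)),
      cat_a = stats::rlnorm(k, log(20), 0.8),
      hfi_a = stats::runif(k, 1, 20),
      hfi_sp = stats::runif(k, 0.2, 1.2),
      ndvi_a = stats::runif(k, 0.2, 0.7),
      ndvi_sp = stats::runif(k, 0.1, 0.5),
      ndvi_tm = stats::runif(k, 0.05, 0.4))
    Z <- scale(as.matrix(covs[, -1]))
    v_sp <- stats::rlnorm(k, log(0.06), 0.4)
    y_sp <- mu_sp + drop(Z %*% beta_sp) +
      stats::rnorm(k, 0, sqrt(tau2_sp)) + stats::rnorm(k, 0, sqrt(v_sp))
    v_tm <- stats::rlnorm(k_t, log(0.012), 0.4)
    y_tm <- mu_tm + drop(Z[seq_len(k_t), ] %*% beta_tm) +
      stats::rnorm(k_t, 0, sqrt(tau2_tm)) + stats::rnorm(k_t, 0, sqrt(v_tm))
    out <- rbind(
      cbind(data.frame(site_id = covs$site_id, response = "spatial",
                       estimate = y_sp, variance = v_sp), covs[, -1]),
      cbind(data.frame(site_id = covs$site_id[seq_len(k_t)],
                       response = "temporal", estimate = y_tm,
                       variance = v_tm), covs[seq_len(k_t), -1]))
    rownames(out) <- NULL
    attr(out, "truth") <- list(mu_spatial = mu_sp, tau2_spatial = tau2_sp,
                               beta_spatial = beta_sp, mu_temporal = mu_tm,
                               tau2_temporal = tau2_tm,
                               beta_temporal = beta_tm, seed = seed)
    out
  })
}

#' Simulate a GPS track with planted rest clusters
#'
#' A travelling track whose consecutive fixes are > 200 m apart (outside the
#' cluster rule's reach), interrupted by rest bouts whose fixes jitter
#' within `jitter_m` (< 50 m) of a bout anchor -- detectable by construction
#' under the 100-m / 2-day / 3-fix rule.
#'
#' @param n_days Track duration in days (>= 1).
#' @param fixes_per_day Fixes per day (evenly spaced).
#' @param step_km Travel step between consecutive fixes in km (> 0.2).
#' @param rest_bouts Data.frame with `start` (fix index), `n_fixes` (>= 3)
#'   and `jitter_m` (< 50) per bout; bouts replace the travel fixes at those
#'   indices with co-located fixes.
#' @param seed Integer seed.
#' @param lon0,lat0 Track origin.
#' @return ObservationRecord-style data.frame (`unit_id`, `timestamp`,
#'   `lon`, `lat`, `method`, `truth_resting`).
#' @export
simulate_gps_track <- function(n_days, fixes_per_day = 8, step_km = 1,
                               rest_bouts = NULL, seed = 1,
                               lon0 = 30, lat0 = -2) {
  if (n_days < 1) stop("invalid config: n_days must be >= 1")
  if (step_km <= 0.2) stop("invalid config: travel steps must exceed 200 m")
  if (!is.null(rest_bouts) && nrow(rest_bouts) > 0) {
    if (any(rest_bouts$n_fixes < 3)) stop("invalid config: bouts need >= 3 fixes")
    if (any(rest_bouts$jitter_m >= 100))
      stop("invalid config: bout jitter must stay below the search radius")
  }
  n <- n_days * fixes_per_day
  dt <- 86400 / fixes_per_day
  withr::with_seed(seed, {
    # random-heading walk in local km coordinates
    ang <- stats::runif(n, 0, 2 * pi)
    x <- cumsum(step_km * cos(ang)); y <- cumsum(step_km * sin(ang))
    resting <- rep(FALSE, n)
    if (!is.null(rest_bouts)) {
      for (b in seq_len(nrow(rest_bouts))) {
        idx <- rest_bouts$start[b] + seq_len(rest_bouts$n_fixes[b]) - 1
        if (max(idx) > n) stop("invalid config: bout extends past track end")
        jit <- rest_bouts$jitter_m[b] / 1000
        x[idx] <- x[idx[1]] + stats::runif(length(idx), -jit, jit) / sqrt(2)
        y[idx] <- y[idx[1]] + stats::runif(length(idx), -jit, jit) / sqrt(2)
        resting[idx] <- TRUE
        if (max(idx) < n) {  # resume travel from the bout anchor
          shift_x <- x[idx[1]] - x[max(idx) + 1] + step_km
          shift_y <- y[idx[1]] - y[max(idx) + 1]
          later <- (max(idx) + 1):n
          x[later] <- x[later] + shift_x; y[later] <- y[later] + shift_y
        }
      }
    }
    ll <- laea_unproject(x, y, lon0, lat0)
    data.frame(unit_id = "gps_01",
               timestamp = as.POSIXct("2015-06-01", tz = "UTC") +
                 (seq_len(n) - 1) * dt,
               lon = ll$lon, lat = ll$lat, method = "gps",
               truth_resting = resting)
  })
}

#' Simulate a monthly NDVI raster stack with calibrated variability
#'
#' Per month, pixel values are a lognormal multiplicative field around the
#' month mean, empirically rescaled so the realized month mean equals its
#' target exactly and the realized within-month (population) CV equals
#' `target_spatial_cv` exactly; the month means themselves are rescaled
#' around their average to hit `target_temporal_cv`. Values must stay inside
#' `[-1, 1]` or the configuration is rejected.
#'
#' @param n_months Number of months (>= 2).
#' @param grid_shape `c(rows, cols)`, at least 2x2.
#' @param mean_curve Per-month target mean NDVI in (-1, 1) (recycled to
#'   `n_months`); its shape (e.g. a seasonal sinusoid) is kept, its
#'   amplitude rescaled to the temporal target.
#' @param target_spatial_cv,target_temporal_cv Nonnegative CV targets.
#' @param seed Integer seed.
#' @param origin `c(lon, lat)` lower-left corner; `cellsize` in degrees.
#' @param cellsize Cell size (degrees).
#' @param start Date of the first month.
#' @return A [monthly_stack()].
#' @export
simulate_ndvi_stack <- function(n_months, grid_shape, mean_curve,
                                target_spatial_cv = 0.2,
                                target_temporal_cv = 0.15, seed = 1,
                                origin = c(30, -2), cellsize = 0.01,
                                start = as.Date("2015-01-01")) {
  if (n_months < 2) stop("invalid config: need >= 2 months")
  if (any(grid_shape < 2)) stop("invalid config: grid must be >= 2x2")
  mu <- rep_len(mean_curve, n_months)
  m0 <- mean(mu)
  sd0 <- sqrt(mean((mu - m0)^2))
  if (target_temporal_cv > 0) {
    if (sd0 == 0)
      stop("invalid config: constant mean_curve cannot hit a nonzero temporal CV")
    mu <- m0 + (mu - m0) * (target_temporal_cv * abs(m0) / sd0)
  } else mu <- rep(m0, n_months)

  npix <- prod(grid_shape)
  withr::with_seed(seed, {
    grids <- lapply(seq_len(n_months), function(i) {
      if (target_spatial_cv > 0) {
        g <- stats::rlnorm(npix, -log(1 + target_spatial_cv^2) / 2,
                           sqrt(log(1 + target_spatial_cv^2)))
        z <- (g - mean(g)) / sqrt(mean((g - mean(g))^2))  # pop. standardized
        vals <- mu[i] * (1 + target_spatial_cv * z)
      } else vals <- rep(mu[i], npix)
      if (any(vals < -1) || any(vals > 1))
        stop("invalid config: CV targets force NDVI outside [-1, 1]")
      grid_raster(matrix(vals, grid_shape[1], grid_shape[2]),
                  origin[1], origin[2], cellsize)
    })
    monthly_stack(seq(start, by = "month", length.out = n_months), grids)
  })
}
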