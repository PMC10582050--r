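#' Buffer radius from study area
#'
#' Radius (km) of the circular buffer whose area equals the study area:
#' `r = sqrt(area / pi)`. The uniform-buffer variant applies the minimum
#' study-area size across the dataset to every site.
#'
#' @param area_km2 Study area in square km (> 0).
#' @return Radius in km.
#' @export
buffer_radius <- function(area_km2) {
  if (any(!is.finite(area_km2)) || any(area_km2 <= 0))
    stop("study area must be positive")
  sqrt(area_km2 / pi)
}

#' Zonal mean and coefficient of variation over a circular buffer
#'
#' Cells whose centres fall within `radius_km` of the buffer centre (great
#' circle) are included; nodata cells are excluded. The CV uses the
#' population SD (divisor n).
#'
#' @param r A [grid_raster()].
#' @param center `c(lon, lat)` of the buffer centre.
#' @param radius_km Buffer radius in km.
#' @return List with `mean`, `cv`, `n_cells`.
#' @export
zonal_mean_cv <- function(r, center, radius_km) {
  cells <- raster_cells(r)
  d <- gc_distance_km(center[1], center[2], cells$lon, cells$lat)
  v <- cells$value[d <= radius_km]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("buffer covers no valid raster cell")
  m <- mean(v)
  sdp <- sqrt(mean((v - m)^2))
  if (m == 0 && sdp > 0) stop("zero mean with nonzero SD: CV undefined")
  list(mean = m, cv = if (sdp == 0) 0 else sdp / m, n_cells = length(v))
}

#' NDVI summary metrics over a buffered site
#'
#' With `mu_i`, `sigma_i` the mean and population SD of buffer pixels in
#' month i (n months):
#' overall mean `NDVI_a = mean(mu_i)`; mean spatial variation
#' `NDVI_sp = mean(sigma_i / mu_i)`; temporal variation
#' `NDVI_tm = sqrt(mean((mu_i - NDVI_a)^2)) / NDVI_a` (population SD of the
#' monthly means over their mean).
#'
#' @param stack A [monthly_stack()].
#' @param center `c(lon, lat)` buffer centre.
#' @param radius_km Buffer radius in km.
#' @param window Optional `c(start, end)` `Date`s restricting the months used
#'   (inclusive); default uses the full stack (long-term variant).
#' @return List with `ndvi_a`, `ndvi_sp`, `ndvi_tm`, `n_months`.
#' @export
ndvi_metrics <- function(stack, center, radius_km, window = NULL) {
  keep <- seq_along(stack$months)
  if (!is.null(window)) {
    window <- as.Date(window)
    keep <- which(stack$months >= window[1] & stack$months <= window[2])
  }
  if (length(keep) < 2) stop("need >= 2 months of NDVI data")
  zs <- lapply(stack$grids[keep], zonal_mean_cv, center = center,
               radius_km = radius_km)
  mu <- vapply(zs, `[[`, 0, "mean")
  cv <- vapply(zs, `[[`, 0, "cv")
  if (any(mu == 0)) stop("zero monthly mean NDVI: spatial CV term undefined")
  ndvi_a <- mean(mu)
  if (ndvi_a == 0) stop("zero overall mean NDVI: temporal CV undefined")
  list(ndvi_a = ndvi_a,
       ndvi_sp = mean(cv),
       ndvi_tm = sqrt(mean((mu - ndvi_a)^2)) / ndvi_a,
       n_months = length(keep))
}

#' Pick the human-footprint epoch closest to a survey's median date
#'
#' The footprint layers exist for 2000 and 2019; the epoch nearer the median
#' study date is used. Dates from 2010-01-01 onward map to 2019 (the exact
#' midpoint tie-breaks to the later epoch).
#'
#' @param median_study_date A `Date` (or string coercible to one).
#' @return 2000 or 2019.
#' @export
select_hfi_year <- function(median_study_date) {
  d <- as.Date(median_study_date)
  ifelse(d < as.Date("2010-01-01"), 2000L, 2019L)
}

#' Site-level covariates from rasters
#'
#' Computes the six moderators for one site: mean cattle density (`cat_a`),
#' mean and spatial CV of the human footprint (`hfi_a`, `hfi_sp`; epoch by
#' [select_hfi_year()]), and the three NDVI metrics.
#'
#' @param site One-row data.frame with `lon`, `lat`, `area_km2`,
#'   `median_date` (and optionally `start_date`, `end_date` for the
#'   study-months NDVI window).
#' @param rasters List with `cattle`, `hfi_2000`, `hfi_2019`
#'   (`grid_raster`s) and `ndvi` (a `monthly_stack`).
#' @param buffer `"site_specific"` (radius from the site's own area) or
#'   `"uniform_min"` (radius from `min_area_km2`).
#' @param ndvi_window `"long_term"` (full stack) or `"study_months"`.
#' @param min_area_km2 Minimum study area across the dataset (required for
#'   the uniform buffer variant).
#' @return One-row data.frame of covariates plus variant tags.
#' @export
site_covariates <- function(site, rasters,
                            buffer = c("site_specific", "uniform_min"),
                            ndvi_window = c("long_term", "study_months"),
                            min_area_km2 = NULL) {
  buffer <- match.arg(buffer)
  ndvi_window <- match.arg(ndvi_window)
  area <- if (buffer == "uniform_min") {
    if (is.null(min_area_km2)) stop("uniform buffer needs min_area_km2")
    min_area_km2
  } else site$area_km2
  rad <- buffer_radius(area)
  ctr <- c(site$lon, site$lat)

  hfi_year <- select_hfi_year(site$median_date)
  hfi <- zonal_mean_cv(rasters[[paste0("hfi_", hfi_year)]], ctr, rad)
  cat_z <- zonal_mean_cv(rasters$cattle, ctr, rad)
  win <- if (ndvi_window == "study_months")
    c(as.Date(site$start_date), as.Date(site$end_date)) else NULL
  nd <- ndvi_metrics(rasters$ndvi, ctr, rad, window = win)

  data.frame(site_id = site$site_id,
             cat_a = cat_z$mean, hfi_a = hfi$mean, hfi_sp = hfi$cv,
             ndvi_a = nd$ndvi_a, ndvi_sp = nd$ndvi_sp, ndvi_tm = nd$ndvi_tm,
             hfi_year = hfi_year, buffer = buffer, ndvi_window = ndvi_window,
             buffer_radius_km = rad)
}

#' Scale covariates and screen for collinearity
#'
#' Centres and scales each moderator to mean 0, SD 1 (sample SD) and flags
#' moderator pairs with `|r| > r_max` (Pearson); flagged pairs must not
#' co-occur in any candidate meta-regression model.
#'
#' @param covariates Data.frame of numeric moderator columns (any non-numeric
#'   columns are carried through untouched).
#' @param r_max Correlation threshold (default 0.6).
#' @return List with `scaled` (the data.frame with scaled moderators),
#'   `forbidden_pairs` (2-column character matrix) and `correlations`.
#' @export
scale_and_screen <- function(covariates, r_max = 0.6) {
  num <- vapply(covariates, is.numeric, TRUE)
  cols <- names(covariates)[num]
  if (nrow(covariates) < 3) stop("need >= 3 sites to scale and screen")
  out <- covariates
  for (cl in cols) {
    s <- stats::sd(covariates[[cl]])
    if (!is.finite(s) || s == 0)
      stop("zero-variance covariate column: ", cl)
    out[[cl]] <- (covariates[[cl]] - mean(covariates[[cl]])) / s
  }
  cm <- stats::cor(covariates[cols])
  pairs <- which(upper.tri(cm) & abs(cm) > r_max, arr.ind = TRUE)
  fp <- cbind(cols[pairs[, 1]], cols[pairs[, 2]])
  list(scaled = out, forbidden_pairs = fp, correlations = cm)
}
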