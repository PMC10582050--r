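#' Solar elevation angle
#'
#' Geometric solar elevation (no atmospheric refraction) at a location and
#' UTC instant, computed with the NOAA general solar-position equations
#' (low-precision Meeus series; accuracy well within 0.1 degrees over
#' 1990--2025). Nocturnality classification uses the geometric sun height, so
#' refraction is deliberately omitted.
#'
#' @param lat,lon Decimal degrees, WGS84 (`-90 <= lat <= 90`,
#'   `-180 <= lon <= 180`).
#' @param time_utc A `POSIXct` instant (any timezone attribute; the absolute
#'   instant is what matters), or a string parseable by [parse_timestamp_utc()].
#' @return Elevation in degrees, in `[-90, 90]`. Vectorized over all
#'   arguments.
#' @export
solar_elevation <- function(lat, lon, time_utc) {
  if (is.character(time_utc)) time_utc <- parse_timestamp_utc(time_utc)
  stopifnot(inherits(time_utc, "POSIXct"))
  if (any(!is.finite(lat)) || any(lat < -90) || any(lat > 90))
    stop("latitude out of range [-90, 90]")
  if (any(!is.finite(lon)) || any(lon < -180) || any(lon > 180))
    stop("longitude out of range [-180, 180]")

  deg2rad <- pi / 180
  jd <- as.numeric(time_utc) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525

  L0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  M  <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e  <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  C  <- sin(M * deg2rad) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
        sin(2 * M * deg2rad) * (0.019993 - 0.000101 * jc) +
        sin(3 * M * deg2rad) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * deg2rad)
  eps0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  eps  <- eps0 + 0.00256 * cos(omega * deg2rad)
  decl <- asin(sin(eps * deg2rad) * sin(app_long * deg2rad))

  y <- tan(eps * deg2rad / 2)^2
  eqtime <- 4 / deg2rad * (y * sin(2 * L0 * deg2rad) -
                           2 * e * sin(M * deg2rad) +
                           4 * e * y * sin(M * deg2rad) * cos(2 * L0 * deg2rad) -
                           0.5 * y^2 * sin(4 * L0 * deg2rad) -
                           1.25 * e^2 * sin(2 * M * deg2rad))

  secs <- as.numeric(time_utc) %% 86400
  tst <- (secs / 60 + eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180
  ha <- ifelse(ha < -180, ha + 360, ha)

  cosz <- sin(lat * deg2rad) * sin(decl) +
          cos(lat * deg2rad) * cos(decl) * cos(ha * deg2rad)
  cosz <- pmin(1, pmax(-1, cosz))
  90 - acos(cosz) / deg2rad
}

#' Classify observations as nocturnal
#'
#' An observation is nocturnal when the sun is lower than `threshold_deg`
#' below the horizon (default -6 degrees, i.e. beyond civil twilight). The
#' comparison is strict: elevation exactly at the threshold is diurnal.
#' Studies that define night differently can override the threshold.
#'
#' @param records Data.frame with `lat`, `lon` and `timestamp` (POSIXct or
#'   ISO-8601 strings with offset) columns; rows missing coordinates fall back
#'   to `fallback_lat`/`fallback_lon` (e.g. the site centroid) when supplied.
#' @param threshold_deg Solar elevation cutoff in degrees (default -6).
#' @param fallback_lat,fallback_lon Optional site-centroid coordinates used
#'   where a record has no coordinates.
#' @return Logical vector, `TRUE` for nocturnal.
#' @export
classify_nocturnal <- function(records, threshold_deg = -6,
                               fallback_lat = NULL, fallback_lon = NULL) {
  lat <- records$lat; lon <- records$lon
  if (!is.null(fallback_lat)) lat[is.na(lat)] <- fallback_lat
  if (!is.null(fallback_lon)) lon[is.na(lon)] <- fallback_lon
  if (any(is.na(lat) | is.na(lon)))
    stop("records without coordinates and no site centroid fallback supplied")
  elev <- solar_elevation(lat, lon, records$timestamp)
  elev < threshold_deg
}

#' Proportion of active observations that are nocturnal
#'
#' @param active Logical (or tri-state character) activity flags; only rows
#'   flagged active contribute.
#' @param nocturnal Logical nocturnality flags.
#' @return List with `p` (nocturnal proportion among active observations) and
#'   `n` (number of active observations), the inputs to the log
#'   response-ratio sampling variance.
#' @export
nocturnal_proportion <- function(active, nocturnal) {
  if (is.character(active)) active <- active == "active"
  keep <- which(active)
  if (length(keep) == 0L)
    stop("no active observations in group; proportion undefined")
  if (any(is.na(nocturnal[keep])))
    stop("active observations with missing nocturnality flag")
  list(p = mean(nocturnal[keep]), n = length(keep))
}
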