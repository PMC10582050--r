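#' @keywords internal
"_PACKAGE"

# Mean Earth radius (km), consistent with the haversine convention used
# throughout: sub-metre error at the 100-m scales the cluster rule operates on.
.EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between points
#'
#' Haversine distance on the WGS84 sphere via \pkg{geosphere}.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @return Distance in kilometres (vectorized).
#' @export
gc_distance_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = .EARTH_RADIUS_KM * 1000) / 1000
}

#' Local azimuthal equal-area projection
#'
#' Forward/inverse Lambert azimuthal equal-area projection on a sphere,
#' centred on a site centroid. Used for grid construction so that square
#' cells keep their nominal area at study scale.
#'
#' @param lon,lat Points to project (decimal degrees).
#' @param lon0,lat0 Projection centre (decimal degrees).
#' @return `laea_project`: data.frame with `x`, `y` in km.
#' @export
laea_project <- function(lon, lat, lon0, lat0) {
  R <- .EARTH_RADIUS_KM
  phi <- lat * pi / 180; lam <- lon * pi / 180
  phi0 <- lat0 * pi / 180; lam0 <- lon0 * pi / 180
  dl <- lam - lam0
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dl)
  kp <- sqrt(2 / denom)
  data.frame(x = R * kp * cos(phi) * sin(dl),
             y = R * kp * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dl)))
}

#' @rdname laea_project
#' @param x,y Projected coordinates in km.
#' @return `laea_unproject`: data.frame with `lon`, `lat` in decimal degrees.
#' @export
laea_unproject <- function(x, y, lon0, lat0) {
  R <- .EARTH_RADIUS_KM
  phi0 <- lat0 * pi / 180; lam0 <- lon0 * pi / 180
  rho <- sqrt(x^2 + y^2)
  out <- data.frame(lon = rep(lon0, length(x)), lat = rep(lat0, length(x)))
  nz <- rho > 0
  if (any(nz)) {
    c_ang <- 2 * asin(pmin(1, rho[nz] / (2 * R)))
    phi <- asin(cos(c_ang) * sin(phi0) +
                  y[nz] * sin(c_ang) * cos(phi0) / rho[nz])
    lam <- lam0 + atan2(x[nz] * sin(c_ang),
                        rho[nz] * cos(phi0) * cos(c_ang) -
                          y[nz] * sin(phi0) * sin(c_ang))
    out$lon[nz] <- lam * 180 / pi
    out$lat[nz] <- phi * 180 / pi
  }
  out
}
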