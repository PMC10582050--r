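#' Mean daily displacement of a GPS track
#'
#' Mean over consecutive calendar-day pairs of the great-circle distance
#' between the first fix of day t and the first fix of day t+1. Used to set
#' the grid-cell side for sites sampled by GPS without natural sample units.
#'
#' @param track Data.frame with `lon`, `lat`, `timestamp` (POSIXct, UTC).
#' @return Displacement in km, or `NA_real_` (with a warning) when the track
#'   has no pair of consecutive calendar days -- callers then fall back to a
#'   1-km grid.
#' @export
mean_daily_displacement <- function(track) {
  ts <- track$timestamp
  if (is.character(ts)) ts <- parse_timestamp_utc(ts)
  day <- as.Date(ts, tz = "UTC")
  first_idx <- tapply(seq_along(day), day, function(i) i[which.min(as.numeric(ts[i]))])
  days <- as.Date(names(first_idx))
  if (length(days) < 2) {
    warning("track spans < 2 calendar days; no displacement computable")
    return(NA_real_)
  }
  i1 <- which(diff(days) == 1)
  if (length(i1) == 0) {
    warning("no consecutive calendar-day pairs in track")
    return(NA_real_)
  }
  a <- unlist(first_idx[i1]); b <- unlist(first_idx[i1 + 1])
  mean(gc_distance_km(track$lon[a], track$lat[a], track$lon[b], track$lat[b]))
}

#' Build a square sample-unit grid over a site
#'
#' Axis-aligned square cells of side `cell_side_km` in a local azimuthal
#' equal-area projection centred on the site centroid, covering the bounding
#' box of the supplied extent.
#'
#' @param site_extent Data.frame of `lon`, `lat` points whose bounding box
#'   the grid must cover (e.g. the observations).
#' @param cell_side_km Cell side in km (> 0); cell area is its square.
#' @param centroid Optional `c(lon, lat)` projection centre; defaults to the
#'   extent midpoint.
#' @return Data.frame of `SampleUnit`s: `unit_id`, projected cell-centre
#'   `x`, `y` (km), centroid `lon`, `lat`, and the grid metadata as
#'   attributes (`cell_side_km`, `centroid`).
#' @export
build_grid <- function(site_extent, cell_side_km, centroid = NULL) {
  if (!is.finite(cell_side_km) || cell_side_km <= 0)
    stop("cell_side_km must be > 0")
  if (nrow(site_extent) == 0) stop("empty site extent")
  if (is.null(centroid))
    centroid <- c(mean(range(site_extent$lon)), mean(range(site_extent$lat)))
  pr <- laea_project(site_extent$lon, site_extent$lat, centroid[1], centroid[2])
  s <- cell_side_km
  ix <- floor(range(pr$x) / s); iy <- floor(range(pr$y) / s)
  g <- expand.grid(ix = ix[1]:ix[2], iy = iy[1]:iy[2])
  cx <- (g$ix + 0.5) * s; cy <- (g$iy + 0.5) * s
  ll <- laea_unproject(cx, cy, centroid[1], centroid[2])
  out <- data.frame(unit_id = sprintf("cell_%d_%d", g$ix, g$iy),
                    x = cx, y = cy, lon = ll$lon, lat = ll$lat)
  attr(out, "cell_side_km") <- s
  attr(out, "centroid") <- centroid
  out
}

#' Assign points to grid cells
#'
#' @param lon,lat Point coordinates.
#' @param grid A grid from [build_grid()].
#' @return Character vector of `unit_id`s (cell containing each point).
#' @export
grid_cell_of <- function(lon, lat, grid) {
  centroid <- attr(grid, "centroid"); s <- attr(grid, "cell_side_km")
  pr <- laea_project(lon, lat, centroid[1], centroid[2])
  sprintf("cell_%d_%d", floor(pr$x / s), floor(pr$y / s))
}

#' Dichotomize sample units into low and high disturbance
#'
#' Quartile rule: units at or below the 1st quartile of the
#' disturbed-orientation metric are `low`, at or above the 3rd quartile
#' `high`, the middle excluded. If either group would hold fewer than
#' `min_group` units, a median split is used instead (`low`: <= median,
#' `high`: > median; nothing excluded). Quantiles use the type-7
#' linear-interpolation convention.
#'
#' @param units Data.frame with a finite `disturbance_value` column.
#' @param direction `"higher_is_disturbed"` (default) or
#'   `"lower_is_disturbed"` (e.g. distance to village): with the latter the
#'   raw metric is negated before cutoffs, so small raw values land in the
#'   high-disturbance group.
#' @param min_group Minimum units per group for the quartile mode
#'   (default 60, from a two-sample t-test power argument; see
#'   [ttest_power_n()]).
#' @return `units` with `category` factor (`low`/`high`/`excluded`) and a
#'   `mode` attribute (`"quartile"` or `"median"`).
#' @export
assign_categories <- function(units, direction = c("higher_is_disturbed",
                                                   "lower_is_disturbed"),
                              min_group = 60) {
  direction <- match.arg(direction)
  v <- units$disturbance_value
  if (any(!is.finite(v))) stop("non-finite disturbance values")
  if (length(unique(v)) == 1L) stop("degenerate disturbance metric: all values identical")
  if (direction == "lower_is_disturbed") v <- -v

  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  low <- v <= q[1]; high <- v >= q[3]
  if (sum(low) < min_group || sum(high) < min_group) {
    mode <- "median"
    low <- v <= q[2]; high <- v > q[2]
  } else mode <- "quartile"

  cat <- rep("excluded", length(v))
  cat[low] <- "low"; cat[high] <- "high"
  units$category <- factor(cat, levels = c("low", "high", "excluded"))
  attr(units, "mode") <- mode
  units
}

#' Summarize space use and nocturnality by disturbance group
#'
#' The per-unit space-use value is the count of active observations in the
#' unit (optionally divided by a per-unit `effort` column). Group mean, SD
#' (sample, n-1) and unit count feed Hedges' d; pooled nocturnal/active
#' counts feed the log response ratio.
#'
#' @param obs Observation table with `unit_id`, `active`, `nocturnal`.
#' @param units Categorized unit table from [assign_categories()].
#' @param effort_normalize Divide unit counts by `units$effort` when `TRUE`
#'   (default `FALSE`; study-native effort is rarely reconstructable).
#' @return List of two per-group summaries (`low`, `high`), each with
#'   `values`, `mean`, `sd`, `n_units`, `nocturnal`, `active`.
#' @export
summarize_groups <- function(obs, units, effort_normalize = FALSE) {
  stopifnot(!is.null(units$category))
  act <- obs[obs$active %in% TRUE, , drop = FALSE]
  one <- function(gr) {
    u <- units[units$category == gr, , drop = FALSE]
    counts <- vapply(u$unit_id, function(id) sum(act$unit_id == id), 0)
    if (effort_normalize) {
      if (is.null(u$effort)) stop("effort_normalize = TRUE but no effort column")
      counts <- counts / u$effort
    }
    in_gr <- act$unit_id %in% u$unit_id
    list(values = unname(counts), mean = mean(counts),
         sd = stats::sd(counts), n_units = nrow(u),
         nocturnal = sum(act$nocturnal[in_gr] %in% TRUE),
         active = sum(in_gr))
  }
  out <- list(low = one("low"), high = one("high"))
  for (gr in c("low", "high"))
    if (out[[gr]]$n_units < 2)
      warning(sprintf("group '%s' has < 2 units; SMD unavailable", gr))
  out
}
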