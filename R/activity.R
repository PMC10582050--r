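#' Sequential GPS cluster detection
#'
#' Single-pass sequential clustering of a GPS track to separate resting
#' (clustered) from active fixes. A candidate cluster opens at the first
#' unassigned fix; each subsequent fix joins if it lies within `radius_m` of
#' the running centroid (recomputed after every addition) AND within
#' `window_days` of the cluster's last member. A fix that fails either test
#' closes the current candidate -- committed as a cluster if it holds at
#' least `min_fixes` members, otherwise dissolved back to active -- and seeds
#' the next candidate. "More than 2 locations" is read strictly, so the
#' default `min_fixes` is 3.
#'
#' Camera-trap and direct observations are never passed here: all independent
#' detections from those methods are treated as active.
#'
#' @param track Data.frame for a single unit: columns `lon`, `lat`,
#'   `timestamp` (POSIXct), strictly increasing in time.
#' @param radius_m Search radius in metres (default 100).
#' @param window_days Temporal window in days (default 2).
#' @param min_fixes Minimum cluster size (default 3).
#' @return List with `cluster` (integer per fix; 0 = unclustered/active),
#'   `active` (logical per fix) and `clusters` (data.frame: id, centroid
#'   lon/lat, first/last timestamp, n).
#' @export
detect_clusters <- function(track, radius_m = 100, window_days = 2,
                            min_fixes = 3) {
  stopifnot(is.data.frame(track), nrow(track) >= 1)
  ts <- track$timestamp
  if (is.character(ts)) ts <- parse_timestamp_utc(ts)
  if (is.unsorted(as.numeric(ts), strictly = TRUE))
    stop("track timestamps must be strictly increasing within a unit")
  n <- nrow(track)
  cluster <- integer(n)
  window_s <- window_days * 86400

  members <- 1L            # indices of the open candidate
  cent_lon <- track$lon[1]; cent_lat <- track$lat[1]
  next_id <- 0L

  close_candidate <- function() {
    if (length(members) >= min_fixes) {
      next_id <<- next_id + 1L
      cluster[members] <<- next_id
    }
  }

  for (i in seq_len(n)[-1]) {
    gap_ok <- as.numeric(ts[i]) - as.numeric(ts[members[length(members)]]) <= window_s
    dist_ok <- gap_ok &&
      gc_distance_km(cent_lon, cent_lat, track$lon[i], track$lat[i]) * 1000 <= radius_m
    if (dist_ok) {
      members <- c(members, i)
      cent_lon <- mean(track$lon[members])
      cent_lat <- mean(track$lat[members])
    } else {
      close_candidate()
      members <- i
      cent_lon <- track$lon[i]; cent_lat <- track$lat[i]
    }
  }
  close_candidate()

  ids <- seq_len(next_id)
  clusters <- data.frame(
    id = ids,
    centroid_lon = vapply(ids, function(k) mean(track$lon[cluster == k]), 0),
    centroid_lat = vapply(ids, function(k) mean(track$lat[cluster == k]), 0),
    first = if (next_id) do.call(c, lapply(ids, function(k) min(ts[cluster == k]))) else ts[0],
    last  = if (next_id) do.call(c, lapply(ids, function(k) max(ts[cluster == k]))) else ts[0],
    n = vapply(ids, function(k) sum(cluster == k), 0L)
  )
  list(cluster = cluster, active = cluster == 0L, clusters = clusters)
}

#' Flag activity for a mixed-method observation table
#'
#' GPS records are run through [detect_clusters()] per unit; clustered fixes
#' are inactive, the rest active. Camera and direct records are active by
#' definition.
#'
#' @param obs Observation table (`site_id`, `unit_id`, `timestamp`, `lon`,
#'   `lat`, `method`).
#' @inheritParams detect_clusters
#' @return `obs` with `active` (logical) and `cluster` (integer) columns.
#' @export
flag_activity <- function(obs, radius_m = 100, window_days = 2, min_fixes = 3) {
  obs$active <- TRUE
  obs$cluster <- 0L
  gps <- obs$method == "gps"
  for (u in unique(obs$unit_id[gps])) {
    sel <- which(gps & obs$unit_id == u)
    sel <- sel[order(obs$timestamp[sel])]
    res <- detect_clusters(obs[sel, ], radius_m, window_days, min_fixes)
    obs$active[sel] <- res$active
    obs$cluster[sel] <- res$cluster
  }
  obs
}
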