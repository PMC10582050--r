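#' Parse ISO-8601 timestamps to UTC
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS` with `Z`, `+HH:MM` or `+HHMM` offsets (a
#' space instead of `T` also works). Strings without an offset need
#' `default_offset` (hours east of UTC, e.g. a per-site configuration).
#'
#' @param x Character vector.
#' @param default_offset Offset in hours applied to offset-free strings
#'   (default `NULL`: such strings are an error).
#' @return POSIXct in UTC; unparseable entries are `NA`.
#' @export
parse_timestamp_utc <- function(x, default_offset = NULL) {
  x <- trimws(x)
  x <- sub(" ", "T", x, fixed = TRUE)
  has_offset <- grepl("(Z|[+-]\\d{2}:?\\d{2})$", x)
  x2 <- sub("Z$", "+0000", x)
  x2 <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", x2)
  out <- rep(as.POSIXct(NA), length(x))
  if (any(has_offset))
    out[has_offset] <- as.POSIXct(x2[has_offset],
                                  format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  if (any(!has_offset)) {
    if (is.null(default_offset))
      stop("timestamps without UTC offset and no site default offset configured")
    base <- as.POSIXct(x2[!has_offset], format = "%Y-%m-%dT%H:%M:%S",
                       tz = "UTC")
    out[!has_offset] <- base - default_offset * 3600
  }
  attr(out, "tzone") <- "UTC"
  out
}

#' Read an observation table
#'
#' CSV with columns `site_id`, `unit_id`, `timestamp` (ISO-8601 with
#' offset), `lon`, `lat`, `method` (gps/camera/direct). Rows with
#' out-of-range coordinates, unknown methods or unparseable timestamps are
#' dropped with a report; more than `max_bad_fraction` bad rows aborts.
#'
#' @param path CSV path.
#' @param default_offset Per-site UTC offset (hours) for offset-free
#'   timestamps.
#' @param max_bad_fraction Tolerated fraction of rejected rows (default 0.01).
#' @return Data.frame of typed records; attribute `validation` holds the
#'   per-reason rejected row numbers.
#' @export
read_observations <- function(path, default_offset = NULL,
                              max_bad_fraction = 0.01) {
  req <- c("site_id", "unit_id", "timestamp", "lon", "lat", "method")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("observation file missing required column(s): ",
         paste(missing, collapse = ", "))
  ts <- suppressWarnings(parse_timestamp_utc(df$timestamp, default_offset))
  bad <- list(
    timestamp = which(is.na(ts)),
    coordinates = which(!is.finite(df$lon) | !is.finite(df$lat) |
                          df$lon < -180 | df$lon > 180 |
                          df$lat < -90 | df$lat > 90),
    method = which(!df$method %in% c("gps", "camera", "direct")))
  drop <- sort(unique(unlist(bad)))
  if (length(drop) > max_bad_fraction * nrow(df))
    stop(sprintf("%d of %d rows invalid (e.g. rows %s)", length(drop),
                 nrow(df), paste(utils::head(drop, 5), collapse = ", ")))
  df$timestamp <- ts
  if (length(drop)) df <- df[-drop, , drop = FALSE]
  attr(df, "validation") <- bad
  df
}

#' @rdname read_observations
#' @param obs Observation data.frame to write (timestamps POSIXct, stored as
#'   ISO-8601 UTC).
#' @export
write_observations <- function(obs, path) {
  out <- obs
  out$timestamp <- format(obs$timestamp, "%Y-%m-%dT%H:%M:%S+00:00",
                          tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a pipeline configuration from YAML
#'
#' Thin wrapper turning a `yaml` config (file paths for the site table,
#' observations and rasters; parameter blocks `activity`, `disturbance`,
#' `covariates`, `meta`; `seed`) into the in-memory config list
#' [run_pipeline()] consumes. Paths are resolved relative to the YAML file.
#'
#' @param path YAML file.
#' @return Config list with tables loaded.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(p) if (is.null(p)) NULL else file.path(base, p)
  if (!is.null(cfg$sites_csv)) {
    cfg$sites <- utils::read.csv(rel(cfg$sites_csv), stringsAsFactors = FALSE)
    cfg$sites_csv <- NULL
  }
  if (!is.null(cfg$observations_csv)) {
    cfg$observations <- read_observations(rel(cfg$observations_csv),
                                          cfg$default_offset)
    cfg$observations_csv <- NULL
  }
  if (!is.null(cfg$units_csv)) {
    cfg$units <- utils::read.csv(rel(cfg$units_csv), stringsAsFactors = FALSE)
    cfg$units_csv <- NULL
  }
  if (!is.null(cfg$ndvi_dir)) {
    cfg$rasters$ndvi <- read_monthly_stack(rel(cfg$ndvi_dir))
    cfg$ndvi_dir <- NULL
  }
  for (nm in c("hfi_2000", "hfi_2019", "cattle")) {
    key <- paste0(nm, "_asc")
    if (!is.null(cfg[[key]])) {
      cfg$rasters[[nm]] <- read_ascii_grid(rel(cfg[[key]]))
      cfg[[key]] <- NULL
    }
  }
  cfg
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

.default <- function(x, d) if (is.null(x)) d else x

#' Run the full meta-analysis pipeline
#'
#' Chains the method's stages: activity classification (GPS cluster rule,
#' solar-elevation nocturnality), disturbance dichotomization
#' (quartile-or-median rule), per-site effect sizes (Hedges' d, log response
#' ratio), optional raster covariates, and ML meta-regression with the
#' all-subsets AICc moderator search. Deterministic given the config.
#'
#' @param config List with:
#'   `sites` (site_id, lon, lat, area_km2, start_date, end_date,
#'   median_date, method, temporal_eligible);
#'   `observations` (ObservationRecord table);
#'   optional `units` (unit_id, site_id, lon, lat, disturbance_value) --
#'   when absent, GPS sites get a displacement-sized grid with disturbance
#'   values extracted from the footprint raster;
#'   optional `rasters` (cattle, hfi_2000, hfi_2019, ndvi) for covariates;
#'   parameter blocks `activity` (radius_m, window_days, min_fixes,
#'   twilight_deg), `disturbance` (direction, min_group, cell_side_km),
#'   `covariates` (buffer, ndvi_window), `meta` (search).
#' @return Result bundle: `effects`, `covariates`, `models` (per response:
#'   intercept-only fit, heterogeneity, QE; search table when requested),
#'   `forest`, `provenance`.
#' @export
run_pipeline <- function(config) {
  act <- config$activity
  dis <- config$disturbance
  sites <- config$sites
  obs_all <- config$observations
  stage <- function(name, site, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed at site '%s': %s",
                   name, site, conditionMessage(e)), call. = FALSE))
  }

  effects <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    obs <- obs_all[obs_all$site_id == s$site_id, , drop = FALSE]
    if (nrow(obs) == 0) stop("no observations for site ", s$site_id)

    obs <- stage("activity", s$site_id,
      flag_activity(obs, .default(act$radius_m, 100),
                    .default(act$window_days, 2), .default(act$min_fixes, 3)))
    obs$nocturnal <- stage("nocturnality", s$site_id,
      classify_nocturnal(obs, .default(act$twilight_deg, -6),
                         fallback_lat = s$lat, fallback_lon = s$lon))

    if (!is.null(config$units)) {
      units <- config$units[config$units$site_id == s$site_id, , drop = FALSE]
    } else {
      units <- stage("gridding", s$site_id, {
        gps <- obs[obs$method == "gps", , drop = FALSE]
        side <- .default(dis$cell_side_km, NA)
        if (is.na(side)) {
          side <- if (nrow(gps) > 1)
            suppressWarnings(mean_daily_displacement(gps)) else NA
          if (is.na(side)) side <- 1
        }
        g <- build_grid(obs, side, centroid = c(s$lon, s$lat))
        if (is.null(config$rasters$hfi_2000))
          stop("no unit table and no footprint raster to score the grid")
        yr <- select_hfi_year(s$median_date)
        g$disturbance_value <- raster_extract(
          config$rasters[[paste0("hfi_", yr)]], g$lon, g$lat)
        g$site_id <- s$site_id
        obs$unit_id <- grid_cell_of(obs$lon, obs$lat, g)
        g[is.finite(g$disturbance_value), , drop = FALSE]
      })
    }
    units <- stage("dichotomization", s$site_id,
      assign_categories(units, .default(dis$direction, "higher_is_disturbed"),
                        .default(dis$min_group, 60)))
    groups <- stage("group summary", s$site_id,
      suppressWarnings(summarize_groups(obs, units)))
    effects[[s$site_id]] <- stage("effect sizes", s$site_id,
      site_effect_sizes(groups, s$site_id,
                        .default(s$temporal_eligible, TRUE)))
  }
  effects <- do.call(rbind, c(effects, list(make.row.names = FALSE)))

  covariates <- NULL
  screened <- NULL
  if (!is.null(config$rasters) && !is.null(config$rasters$ndvi)) {
    cv <- lapply(seq_len(nrow(sites)), function(i)
      stage("covariates", sites$site_id[i],
        site_covariates(sites[i, ], config$rasters,
                        .default(config$covariates$buffer, "site_specific"),
                        .default(config$covariates$ndvi_window, "long_term"),
                        min_area_km2 = min(sites$area_km2))))
    covariates <- do.call(rbind, cv)
    screened <- scale_and_screen(
      covariates[, c("cat_a", "hfi_a", "hfi_sp", "ndvi_a", "ndvi_sp",
                     "ndvi_tm")])
  }

  models <- list()
  forest <- list()
  for (resp in unique(effects$response)) {
    ef <- effects[effects$response == resp, , drop = FALSE]
    if (nrow(ef) < 3) next
    fit <- fit_ml_meta(ef$estimate, ef$variance)
    entry <- list(fit = fit, heterogeneity = heterogeneity(fit),
                  qe = qe_test(fit), aicc = aicc(fit))
    if (isTRUE(.default(config$meta$search, FALSE)) && !is.null(screened)) {
      idx <- match(ef$site_id, covariates$site_id)
      mods <- screened$scaled[idx, c("cat_a", "hfi_a", "hfi_sp", "ndvi_a",
                                     "ndvi_sp", "ndvi_tm"), drop = FALSE]
      entry$search <- model_search(ef$estimate, ef$variance, mods,
                                   forbidden_pairs = screened$forbidden_pairs)
    }
    models[[resp]] <- entry
    forest[[resp]] <- forest_data(ef)
  }

  list(effects = effects, covariates = covariates, models = models,
       forest = forest,
       provenance = list(
         package_version = as.character(utils::packageVersion("carnmeta")),
         r_version = R.version.string,
         config_hash = .config_hash(config),
         parameters = config[c("activity", "disturbance", "covariates",
                               "meta", "seed")],
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
}
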