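#' Lightweight geographic grid raster
#'
#' A minimal single-band raster: a numeric matrix (rows = north to south) on
#' a regular lon/lat grid. Sufficient for zonal statistics over circular
#' buffers at study scale; reading and writing use the plain-text ESRI
#' ASCII-grid format.
#'
#' @param values Numeric matrix (first row = northernmost).
#' @param xll,yll Lower-left corner of the grid (decimal degrees).
#' @param cellsize Cell size in decimal degrees.
#' @param nodata Value treated as missing (default -9999).
#' @return Object of class `grid_raster`.
#' @export
grid_raster <- function(values, xll, yll, cellsize, nodata = -9999) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata),
            class = "grid_raster")
}

#' Cell-centre coordinates of a grid raster
#' @param r A `grid_raster`.
#' @return Data.frame `lon`, `lat`, `value` (one row per cell, NA for nodata).
#' @export
raster_cells <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  lon <- r$xll + (seq_len(nc) - 0.5) * r$cellsize
  lat <- r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize  # row 1 = north
  v <- as.vector(t(r$values))  # row-major: row 1 first
  v[v == r$nodata] <- NA
  data.frame(lon = rep(lon, times = nr), lat = rep(lat, each = nc), value = v)
}

#' Read / write ESRI ASCII grids
#'
#' @param path File path (`.asc`).
#' @return `read_ascii_grid`: a `grid_raster`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  keys <- tolower(kv[, 1]); vals <- as.numeric(kv[, 2])
  names(vals) <- keys
  n_hdr <- sum(keys %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                           "cellsize", "nodata_value"))
  body <- scan(path, skip = n_hdr, quiet = TRUE)
  m <- matrix(body, nrow = vals["nrows"], ncol = vals["ncols"], byrow = TRUE)
  nodata <- if ("nodata_value" %in% keys) vals["nodata_value"] else -9999
  m[m == nodata] <- NA
  grid_raster(m, unname(vals["xllcorner"]), unname(vals["yllcorner"]),
              unname(vals["cellsize"]), unname(nodata))
}

#' @rdname read_ascii_grid
#' @param r A `grid_raster` to write.
#' @export
write_ascii_grid <- function(r, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(r$values)),
               sprintf("nrows %d", nrow(r$values)),
               sprintf("xllcorner %.10g", r$xll),
               sprintf("yllcorner %.10g", r$yll),
               sprintf("cellsize %.10g", r$cellsize),
               sprintf("NODATA_value %.10g", r$nodata)), con)
  v <- r$values; v[is.na(v)] <- r$nodata
  utils::write.table(format(v, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract raster values at points
#' @param r A `grid_raster`.
#' @param lon,lat Point coordinates.
#' @return Numeric vector (NA outside the grid or at nodata cells).
#' @export
raster_extract <- function(r, lon, lat) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((lon - r$xll) / r$cellsize) + 1
  row <- nr - floor((lat - r$yll) / r$cellsize)
  ok <- col >= 1 & col <= nc & row >= 1 & row <= nr &
    is.finite(col) & is.finite(row)
  out <- rep(NA_real_, length(lon))
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  out[!is.na(out) & out == r$nodata] <- NA
  out
}

#' Monthly raster stack
#'
#' Ordered stack of same-shape, same-georeference monthly grids (e.g. NDVI).
#'
#' @param months Vector of first-of-month `Date`s, strictly increasing.
#' @param grids List of `grid_raster`s, one per month.
#' @return Object of class `monthly_stack`.
#' @export
monthly_stack <- function(months, grids) {
  months <- as.Date(months)
  stopifnot(length(months) == length(grids), length(months) >= 1,
            !is.unsorted(months, strictly = TRUE))
  shp <- dim(grids[[1]]$values)
  for (g in grids)
    stopifnot(inherits(g, "grid_raster"), identical(dim(g$values), shp),
              isTRUE(all.equal(c(g$xll, g$yll, g$cellsize),
                               c(grids[[1]]$xll, grids[[1]]$yll,
                                 grids[[1]]$cellsize))))
  structure(list(months = months, grids = grids), class = "monthly_stack")
}

#' Write / read a monthly stack as YYYY-MM.asc files
#' @param stack A `monthly_stack`.
#' @param dir Directory for the per-month grids.
#' @export
write_monthly_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack$months))
    write_ascii_grid(stack$grids[[i]],
                     file.path(dir, format(stack$months[i], "%Y-%m.asc")))
  invisible(dir)
}

#' @rdname write_monthly_stack
#' @export
read_monthly_stack <- function(dir) {
  files <- sort(list.files(dir, pattern = "^\\d{4}-\\d{2}\\.asc$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no YYYY-MM.asc files in ", dir)
  months <- as.Date(paste0(sub("\\.asc$", "", basename(files)), "-01"))
  monthly_stack(months, lapply(files, read_ascii_grid))
}
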