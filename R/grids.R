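# Grid containers for monthly temperature stacks and suitability surfaces,
# plus plain-text (ESRI ASCII grid) raster I/O.
#
# Conventions: geographic coordinates (EPSG:4326 semantics), cell-center
# latitudes/longitudes, matrices stored north-up (row 1 = northernmost row),
# square cells, nodata -9999 on disk and NA in memory.

.GRID_NODATA <- -9999

.regular_centers <- function(x, what) {
  if (length(x) < 2) stop(sprintf("%s needs at least 2 cells", what), call. = FALSE)
  d <- diff(x)
  if (any(abs(d - d[1]) > 1e-6)) {
    stop(sprintf("%s cell centers are not regularly spaced", what), call. = FALSE)
  }
  abs(d[1])
}

#' Construct a monthly temperature grid stack
#'
#' Twelve monthly temperature layers (degrees C) on a regular lat/lon grid
#' with a shared land-sea mask.  `NA` cells are nodata; masks and grid are
#' identical across the twelve layers by construction.
#'
#' @param lat Cell-center latitudes, strictly decreasing (north-up), degrees.
#' @param lon Cell-center longitudes, strictly increasing, degrees.
#' @param months Numeric array `[n_lat, n_lon, 12]` of temperatures (C).
#' @param land Logical matrix `[n_lat, n_lon]`; `TRUE` = land cell.
#' @return A `temp_grid_stack` object.
#' @export
temp_grid_stack <- function(lat, lon, months, land) {
  lat <- as.numeric(lat)
  lon <- as.numeric(lon)
  if (is.unsorted(rev(lat), strictly = TRUE)) {
    stop("lat must be strictly decreasing (north-up)", call. = FALSE)
  }
  if (is.unsorted(lon, strictly = TRUE)) {
    stop("lon must be strictly increasing", call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) stop("latitudes outside [-90, 90]", call. = FALSE)
  if (length(dim(months)) != 3 || dim(months)[3] != 12) {
    stop("months must be an [n_lat, n_lon, 12] array: 12 monthly layers required",
         call. = FALSE)
  }
  if (dim(months)[1] != length(lat) || dim(months)[2] != length(lon)) {
    stop("months array dimensions do not match lat/lon", call. = FALSE)
  }
  land <- matrix(as.logical(land), length(lat), length(lon))
  structure(list(lat = lat, lon = lon, months = months, land = land),
            class = "temp_grid_stack")
}

#' @export
print.temp_grid_stack <- function(x, ...) {
  cat(sprintf("<temp_grid_stack> %d x %d cells, 12 months, %.0f%% land\n",
              length(x$lat), length(x$lon), 100 * mean(x$land)))
  invisible(x)
}

#' Construct an annual suitability grid
#'
#' Annual-mean Thermal Habitat Suitability per cell, in `[0, 1]`, `NA` for
#' nodata/masked cells.
#'
#' @param lat,lon Cell-center coordinates as in [temp_grid_stack()].
#' @param values Numeric matrix `[n_lat, n_lon]` in `[0, 1]` or `NA`.
#' @return A `ths_grid` object.
#' @export
ths_grid <- function(lat, lon, values) {
  v <- values[!is.na(values)]
  if (length(v) > 0 && (min(v) < 0 || max(v) > 1)) {
    stop("THS values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon),
                 values = values),
            class = "ths_grid")
}

#' @export
print.ths_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<ths_grid> %d x %d cells, %d unmasked, THS %.3f-%.3f\n",
              length(x$lat), length(x$lon), length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

# Strict grid-alignment check (same centers to 1e-6 degrees); no implicit
# resampling anywhere in the package.
.same_grid <- function(a, b) {
  length(a$lat) == length(b$lat) && length(a$lon) == length(b$lon) &&
    max(abs(a$lat - b$lat)) <= 1e-6 && max(abs(a$lon - b$lon)) <= 1e-6
}

.check_aligned <- function(a, b, what = "grids") {
  if (!.same_grid(a, b)) {
    stop(sprintf("%s are not aligned (same extent/origin/cell size required; no implicit resampling)",
                 what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a matrix as an ESRI ASCII grid
#'
#' Plain-text raster interchange: cell-center coordinates are converted to
#' the lower-left corner origin of the ASCII grid header.  Cells must be
#' square.  Values are written with six significant digits; `NA` becomes the
#' nodata value.
#'
#' @param values Numeric matrix, north-up.
#' @param lat,lon Cell-center coordinates (lat strictly decreasing).
#' @param path Output file path (conventionally `.asc`).
#' @param nodata Nodata sentinel written to file.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, lat, lon, path, nodata = .GRID_NODATA) {
  dlat <- .regular_centers(lat, "lat")
  dlon <- .regular_centers(lon, "lon")
  if (abs(dlat - dlon) > 1e-6) {
    stop("ASCII grid output requires square cells", call. = FALSE)
  }
  header <- c(
    sprintf("ncols %d", ncol(values)),
    sprintf("nrows %d", nrow(values)),
    sprintf("xllcorner %.10g", min(lon) - dlon / 2),
    sprintf("yllcorner %.10g", min(lat) - dlat / 2),
    sprintf("cellsize %.10g", dlon),
    sprintf("NODATA_value %g", nodata)
  )
  m <- values
  m[is.na(m)] <- nodata
  rows <- apply(m, 1, function(r) paste(formatC(r, format = "g", digits = 6),
                                        collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @return List with `values` (matrix, `NA` for nodata), `lat`, `lon`
#'   (cell centers), `cellsize`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop(sprintf("malformed ASCII grid header in %s", path), call. = FALSE)
  }
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows) {
    stop(sprintf("expected %d data rows in %s, found %d",
                 hdr$nrows, path, length(body)), call. = FALSE)
  }
  m <- t(vapply(body, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                numeric(hdr$ncols), USE.NAMES = FALSE))
  m[m == hdr$nodata_value] <- NA
  cs <- hdr$cellsize
  lon <- hdr$xllcorner + cs * (seq_len(hdr$ncols) - 0.5)
  lat_asc <- hdr$yllcorner + cs * (seq_len(hdr$nrows) - 0.5)
  lat <- rev(lat_asc)  # north-up
  list(values = m, lat = lat, lon = lon, cellsize = cs)
}

#' Write a monthly temperature stack to a directory
#'
#' Writes twelve files `<prefix>_01.asc` ... `<prefix>_12.asc` plus a
#' `<prefix>_land.asc` mask layer (1 = land, 0 = sea).
#'
#' @param stack A `temp_grid_stack`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return `dir`, invisibly.
#' @export
write_monthly_stack <- function(stack, dir, prefix = "tavg") {
  stopifnot(inherits(stack, "temp_grid_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (m in 1:12) {
    write_ascii_grid(stack$months[, , m], stack$lat, stack$lon,
                     file.path(dir, sprintf("%s_%02d.asc", prefix, m)))
  }
  write_ascii_grid(matrix(as.numeric(stack$land), nrow(stack$land)),
                   stack$lat, stack$lon,
                   file.path(dir, sprintf("%s_land.asc", prefix)))
  invisible(dir)
}

#' Read a monthly temperature stack from a directory
#'
#' Expects the layout written by [write_monthly_stack()].  Refuses stacks
#' with missing months or inconsistent grids.
#'
#' @param dir Directory containing `<prefix>_01.asc` ... `<prefix>_12.asc`
#'   and `<prefix>_land.asc`.
#' @param prefix File-name prefix.
#' @return A `temp_grid_stack`.
#' @export
read_monthly_stack <- function(dir, prefix = "tavg") {
  paths <- file.path(dir, sprintf("%s_%02d.asc", prefix, 1:12))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop(sprintf("monthly stack in %s is missing month(s): %s",
                 dir, paste(which(missing), collapse = ", ")), call. = FALSE)
  }
  layers <- lapply(paths, read_ascii_grid)
  ref <- layers[[1]]
  for (m in 2:12) {
    l <- layers[[m]]
    if (length(l$lat) != length(ref$lat) || length(l$lon) != length(ref$lon) ||
        abs(l$cellsize - ref$cellsize) > 1e-9 ||
        max(abs(l$lat - ref$lat)) > 1e-6 || max(abs(l$lon - ref$lon)) > 1e-6) {
      stop(sprintf("month %02d grid does not match month 01 grid", m),
           call. = FALSE)
    }
  }
  mask_path <- file.path(dir, sprintf("%s_land.asc", prefix))
  if (!file.exists(mask_path)) {
    stop(sprintf("land mask layer %s is missing", mask_path), call. = FALSE)
  }
  mask <- read_ascii_grid(mask_path)
  if (max(abs(mask$lat - ref$lat)) > 1e-6 || max(abs(mask$lon - ref$lon)) > 1e-6) {
    stop("land mask grid does not match temperature grid", call. = FALSE)
  }
  arr <- array(NA_real_, c(length(ref$lat), length(ref$lon), 12))
  for (m in 1:12) arr[, , m] <- layers[[m]]$values
  temp_grid_stack(ref$lat, ref$lon, arr, mask$values > 0.5)
}
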