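#' Elevation grid container
#'
#' A minimal north-up raster: a numeric matrix whose first row is the
#' northernmost row, plus georeferencing (lower-left corner of the grid in
#' decimal degrees, square cell size) and a nodata marker. Cells equal to
#' the nodata value are treated as missing by every window statistic.
#'
#' @param values numeric matrix of elevations (m); row 1 = north.
#' @param xll,yll lower-left corner coordinates (decimal degrees, WGS84).
#' @param cellsize cell size. Interpreted in degrees for georeferencing;
#'   \code{cell_m} carries the ground size used for areas.
#' @param cell_m ground cell size in metres (for planimetric areas);
#'   default 30.
#' @param nodata value marking missing cells (default -9999).
#' @return object of class \code{"elev_grid"}.
#' @export
elev_grid <- function(values, xll = 0, yll = 0, cellsize = 1,
                      cell_m = 30, nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (cellsize <= 0) stop("'cellsize' must be > 0")
  if (cell_m <= 0) stop("'cell_m' must be > 0")
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, cell_m = cell_m, nodata = nodata),
            class = "elev_grid")
}

#' @export
print.elev_grid <- function(x, ...) {
  cat(sprintf("elev_grid: %d x %d cells, cellsize %g deg (%g m), origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$cell_m,
              x$xll, x$yll))
  v <- grid_values(x)
  cat(sprintf("  elevation range: %g .. %g m (%d nodata cells)\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

# matrix with nodata replaced by NA
grid_values <- function(grid) {
  v <- grid$values
  v[v == grid$nodata] <- NA_real_
  v
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text grid exchange format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header followed by rows of cell
#' values, north row first).
#'
#' @param path file path.
#' @param grid an [elev_grid()].
#' @param cell_m ground cell size in metres to attach on read.
#' @return \code{read_ascii_grid} returns an [elev_grid()];
#'   \code{write_ascii_grid} returns \code{path} invisibly.
#' @export
read_ascii_grid <- function(path, cell_m = 30) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("ASCII grid header missing: ", paste(miss, collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body size does not match header")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  elev_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
            cellsize = hdr$cellsize, cell_m = cell_m,
            nodata = if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "elev_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(grid$values)),
    sprintf("nrows %d", nrow(grid$values)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", grid$nodata)), con)
  utils::write.table(grid$values, con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Monthly climate stack
#'
#' A stack of monthly layers of one climate variable (temperature in
#' degrees C or precipitation in mm) over complete years, stored as a 3-D
#' array \code{[row, col, layer]} with layers ordered Jan year 1, Feb
#' year 1, ..., Dec of the final year. Layer count must be divisible by
#' 12; all layers share the grid's georeferencing.
#'
#' @param layers numeric 3-D array, third dimension a multiple of 12.
#' @param xll,yll,cellsize georeferencing as in [elev_grid()].
#' @return object of class \code{"monthly_stack"}.
#' @export
monthly_stack <- function(layers, xll = 0, yll = 0, cellsize = 1) {
  if (!is.array(layers) || length(dim(layers)) != 3L)
    stop("'layers' must be a 3-D array [row, col, month-layer]")
  if (dim(layers)[3] %% 12L != 0L)
    stop("layer count must be a multiple of 12 (complete years)")
  structure(list(layers = layers, xll = xll, yll = yll,
                 cellsize = cellsize, n_years = dim(layers)[3] %/% 12L),
            class = "monthly_stack")
}

#' Multi-year climate means from a monthly stack
#'
#' \code{mode = "january"} averages the year-wise January layers (used for
#' the January mean-temperature factor). \code{mode = "annual_total_mean"}
#' sums the 12 monthly layers within each year and averages the yearly
#' totals (used for the annual-precipitation factor: the mean annual
#' total, so a stack of constant value c yields 12c).
#'
#' @param stack a [monthly_stack()].
#' @param mode \code{"january"} or \code{"annual_total_mean"}.
#' @return an [elev_grid()]-shaped grid of the requested mean (same
#'   georeferencing; nodata -9999 unused).
#' @export
climate_mean <- function(stack, mode = c("january", "annual_total_mean")) {
  stopifnot(inherits(stack, "monthly_stack"))
  mode <- match.arg(mode)
  Y <- stack$n_years
  d <- dim(stack$layers)
  out <- matrix(0, d[1], d[2])
  if (mode == "january") {
    for (y in seq_len(Y)) out <- out + stack$layers[, , (y - 1L) * 12L + 1L]
    out <- out / Y
  } else {
    for (y in seq_len(Y)) {
      yearly <- matrix(0, d[1], d[2])
      for (m in 1:12) yearly <- yearly + stack$layers[, , (y - 1L) * 12L + m]
      out <- out + yearly
    }
    out <- out / Y
  }
  elev_grid(out, xll = stack$xll, yll = stack$yll,
            cellsize = stack$cellsize)
}

# cell index (row, col) of a lon/lat point; NA when outside the extent
cell_index <- function(grid, lon, lat) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((lon - grid$xll) / grid$cellsize) + 1
  row_from_bottom <- floor((lat - grid$yll) / grid$cellsize) + 1
  row <- nr - row_from_bottom + 1
  ok <- col >= 1 & col <= nc & row >= 1 & row <= nr
  col[!ok] <- NA_integer_; row[!ok] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Sample a grid at point locations
#'
#' Nearest-cell (the cell containing the point) lookup. Points outside
#' the grid extent or landing on nodata cells yield \code{NA} and are
#' flagged, never silently dropped.
#'
#' @param grid an [elev_grid()] (any gridded quantity).
#' @param points data.frame with \code{lon} and \code{lat} columns
#'   (decimal degrees).
#' @return data.frame with columns \code{value}, \code{outside}
#'   (logical: point outside the extent) and \code{nodata} (logical:
#'   point on a nodata cell), one row per point.
#' @export
sample_at_points <- function(grid, points) {
  stopifnot(inherits(grid, "elev_grid"),
            all(c("lon", "lat") %in% names(points)))
  idx <- cell_index(grid, points$lon, points$lat)
  outside <- is.na(idx[, "row"])
  v <- grid_values(grid)
  value <- rep(NA_real_, nrow(points))
  inb <- which(!outside)
  if (length(inb))
    value[inb] <- v[cbind(idx[inb, "row"], idx[inb, "col"])]
  nodata <- !outside & is.na(value)
  if (any(outside))
    warning(sum(outside), " point(s) outside the grid extent; flagged NA")
  data.frame(value = value, outside = outside, nodata = nodata)
}
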