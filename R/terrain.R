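#' Aspect (azimuth of steepest descent) from an elevation grid
#'
#' Central-difference gradients on the interior cells give the downslope
#' azimuth in degrees clockwise from north. Flat cells (both gradients
#' zero) and cells adjacent to nodata are undefined (\code{NA}). Border
#' cells are undefined because the central difference needs both
#' neighbours.
#'
#' @param grid an [elev_grid()], at least 3 x 3 valid cells.
#' @return matrix of azimuths in [0, 360), \code{NA} where undefined,
#'   same shape as the grid.
#' @export
compute_aspect <- function(grid) {
  stopifnot(inherits(grid, "elev_grid"))
  z <- grid_values(grid)
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3L || nc < 3L) stop("grid must be at least 3 x 3")
  az <- matrix(NA_real_, nr, nc)
  h <- 2 * grid$cell_m
  for (i in 2:(nr - 1L)) {
    for (j in 2:(nc - 1L)) {
      e <- z[i, j + 1L]; w <- z[i, j - 1L]
      n <- z[i - 1L, j]; s <- z[i + 1L, j]
      if (anyNA(c(e, w, n, s))) next
      dzdx <- (e - w) / h        # eastward gradient
      dzdy <- (n - s) / h        # northward gradient (row 1 = north)
      if (dzdx == 0 && dzdy == 0) next   # flat: undefined
      a <- atan2(-dzdx, -dzdy) * 180 / pi  # steepest descent = -gradient
      az[i, j] <- (a + 360) %% 360
    }
  }
  az
}

#' Classify aspect azimuth into four slope classes
#'
#' Northern-Hemisphere convention: 1 = shady (N), 2 = semi-shady (NE/NW),
#' 3 = sunny (S), 4 = semi-sunny (SE/SW). Default bins:
#' shady \[315, 360) U \[0, 45); semi-shady \[45, 90) U \[270, 315);
#' sunny \[135, 225); semi-sunny \[90, 135) U \[225, 270). The bin edges
#' are configurable via \code{breaks8}, the eight boundary azimuths in
#' clockwise order starting at the shady/semi-shady edge.
#'
#' Azimuths outside [0, 360) are normalized modulo 360 with a warning;
#' undefined (NA) azimuths stay missing.
#'
#' @param azimuth numeric vector/matrix of azimuths (degrees clockwise
#'   from north) or NA for flat cells.
#' @param breaks8 boundary azimuths, default
#'   \code{c(45, 90, 135, 225, 270, 315)} marking the class transitions.
#' @return integer classes 1-4 with the shape of \code{azimuth};
#'   \code{NA} propagated.
#' @export
classify_aspect <- function(azimuth, breaks8 = c(45, 90, 135, 225, 270, 315)) {
  a <- as.numeric(azimuth)
  bad <- !is.na(a) & (a < 0 | a >= 360)
  if (any(bad)) {
    warning("azimuth outside [0, 360) normalized modulo 360")
    a[bad] <- a[bad] %% 360
  }
  b <- breaks8
  cls <- rep(NA_integer_, length(a))
  ok <- !is.na(a)
  cls[ok & (a >= b[6] | a < b[1])] <- 1L                 # shady: N
  cls[ok & ((a >= b[1] & a < b[2]) | (a >= b[5] & a < b[6]))] <- 2L  # semi-shady
  cls[ok & (a >= b[3] & a < b[4])] <- 3L                 # sunny: S
  cls[ok & ((a >= b[2] & a < b[3]) | (a >= b[4] & a < b[5]))] <- 4L  # semi-sunny
  if (is.matrix(azimuth)) cls <- matrix(cls, nrow(azimuth), ncol(azimuth))
  cls
}

#' Terrain relief over a moving window
#'
#' Relief P = Hmax - Hmin over the valid cells of a centred square
#' window (truncated at the grid border). Cells whose window holds no
#' valid cell are \code{NA}; nodata cells are excluded from the max/min.
#' The window size is a modelling choice (default 3 cells) and
#' is recorded as an attribute of the result.
#'
#' @param grid an [elev_grid()].
#' @param window odd window width in cells, >= 3.
#' @return matrix of relief values (m), attribute \code{"window"}.
#' @export
terrain_relief <- function(grid, window = 3L) {
  stopifnot(inherits(grid, "elev_grid"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3")
  z <- grid_values(grid)
  nr <- nrow(z); nc <- ncol(z)
  half <- window %/% 2L
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- max(1L, i - half):min(nr, i + half)
      cj <- max(1L, j - half):min(nc, j + half)
      w <- z[ri, cj]
      w <- w[!is.na(w)]
      if (length(w) >= 1L) out[i, j] <- max(w) - min(w)
    }
  }
  attr(out, "window") <- window
  out
}

#' Mountaintop effect: summit area above a threshold elevation
#'
#' The planimetric surface area of the mountain lying above a threshold
#' elevation (the forest upper limit): the count of masked cells whose
#' elevation exceeds the threshold, times the cell ground area. A
#' slope-corrected true surface area is available but off by default
#' since planimetric area is the conventional definition here.
#'
#' @param grid an [elev_grid()].
#' @param mountain_mask logical matrix, TRUE for cells belonging to the
#'   mountain; must select at least one cell.
#' @param threshold_elevation elevation (m); strictly-above cells count.
#' @param slope_corrected logical; if TRUE, each qualifying cell's area is
#'   scaled by \code{sqrt(1 + |grad z|^2)} from central differences
#'   (border/flat-neighbour cells fall back to planimetric).
#' @return area in m^2 (0 when no cell qualifies).
#' @export
mountaintop_effect <- function(grid, mountain_mask, threshold_elevation,
                               slope_corrected = FALSE) {
  stopifnot(inherits(grid, "elev_grid"))
  if (!is.logical(mountain_mask) ||
      !identical(dim(mountain_mask), dim(grid$values)))
    stop("'mountain_mask' must be a logical matrix matching the grid")
  if (!any(mountain_mask)) stop("'mountain_mask' selects no cells")
  z <- grid_values(grid)
  qual <- mountain_mask & !is.na(z) & z > threshold_elevation
  cell_area <- grid$cell_m^2
  if (!slope_corrected) return(sum(qual) * cell_area)
  nr <- nrow(z); nc <- ncol(z)
  total <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!qual[i, j]) next
    f <- 1
    if (i > 1L && i < nr && j > 1L && j < nc &&
        !anyNA(c(z[i, j - 1L], z[i, j + 1L], z[i - 1L, j], z[i + 1L, j]))) {
      gx <- (z[i, j + 1L] - z[i, j - 1L]) / (2 * grid$cell_m)
      gy <- (z[i - 1L, j] - z[i + 1L, j]) / (2 * grid$cell_m)
      f <- sqrt(1 + gx^2 + gy^2)
    }
    total <- total + f * cell_area
  }
  total
}

#' Filter location points by elevation and minimum spacing
#'
#' Greedy sequential acceptance in input order: a point is kept iff its
#' elevation is at least \code{min_elevation} and its great-circle
#' (haversine, WGS84) distance to every previously kept point is at least
#' \code{min_spacing}. The result therefore depends on the input order,
#' which is deterministic and documented. Defaults enforce the 400 m
#' inter-point spacing and the 700 m a.s.l. floor used for well-developed
#' altitudinal zonation.
#'
#' @param points data.frame with \code{lon}, \code{lat},
#'   \code{elevation_m} columns.
#' @param min_spacing minimum ground distance between kept points (m).
#' @param min_elevation minimum elevation (m a.s.l.).
#' @return the kept subset of \code{points}; attribute \code{"report"}
#'   is a data.frame of all points with \code{kept} and \code{reason}
#'   (\code{""}, \code{"below_min_elevation"} or \code{"too_close"}).
#' @export
filter_points <- function(points, min_spacing = 400, min_elevation = 700) {
  stopifnot(all(c("lon", "lat", "elevation_m") %in% names(points)))
  n <- nrow(points)
  kept <- logical(n)
  reason <- character(n)
  kept_coords <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    if (is.na(points$elevation_m[i]) || points$elevation_m[i] < min_elevation) {
      reason[i] <- "below_min_elevation"
      next
    }
    p <- c(points$lon[i], points$lat[i])
    if (nrow(kept_coords) > 0) {
      d <- geosphere::distHaversine(p, kept_coords)
      if (any(d < min_spacing)) {
        reason[i] <- "too_close"
        next
      }
    }
    kept[i] <- TRUE
    kept_coords <- rbind(kept_coords, p)
  }
  out <- points[kept, , drop = FALSE]
  attr(out, "report") <- data.frame(
    row = seq_len(n), kept = kept, reason = reason,
    stringsAsFactors = FALSE)
  out
}
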