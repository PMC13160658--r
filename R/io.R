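#' Published per-mountain sensitivity indices for 28 Northern-Hemisphere
#' mountains
#'
#' A reference summary table of temperature and precipitation
#' sensitivity indices (scale x100) for the upper limits of montane
#' deciduous broad-leaved forests in 28 Northern-Hemisphere mountains,
#' with mean coordinates, study-region and moisture-class labels, and
#' the published comprehensive-index and contribution-rate columns for
#' cross-checking. Used by examples and by the arithmetic consistency
#' checks; note the Crimean row's published contribution rates are
#' internally inconsistent with its index pair (a known misprint) — the
#' package recomputes contributions from the indices.
#'
#' @return data.frame with columns \code{mountain}, \code{latitude},
#'   \code{longitude}, \code{tsi}, \code{psi}, \code{csi_printed},
#'   \code{p_temp_printed_pct}, \code{p_precip_printed_pct},
#'   \code{region}, \code{moisture}.
#' @export
nh_mountain_indices <- function() {
  path <- system.file("extdata", "nh_mountain_indices.csv",
                      package = "cloudsens", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# required columns of a location-point table
point_columns <- function() {
  c("mountain_id", "site_id", "point_id", "lon", "lat", "elevation_m",
    impact_factors())
}

#' Read a location-point table
#'
#' Header-driven CSV reader for point tables (column order free).
#' Rows with unparsable or missing numeric fields are collected into an
#' error report attached as attribute \code{"errors"}, never silently
#' dropped.
#'
#' @param path CSV path.
#' @return data.frame of well-formed points; attribute \code{"errors"}
#'   holds the malformed rows with a \code{problem} column.
#' @export
read_points <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- point_columns()
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("point table is missing required column(s): ",
         paste(miss, collapse = ", "))
  num_cols <- setdiff(need, c("mountain_id", "site_id", "point_id"))
  parsed <- raw
  bad <- rep(FALSE, nrow(raw))
  problem <- rep("", nrow(raw))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    newly_bad <- !bad & (is.na(v))
    problem[newly_bad] <- paste0("unparsable ", cn)
    bad <- bad | is.na(v)
    parsed[[cn]] <- v
  }
  good <- parsed[!bad, need, drop = FALSE]
  rownames(good) <- NULL
  errors <- cbind(raw[bad, , drop = FALSE],
                  problem = problem[bad])
  rownames(errors) <- NULL
  attr(good, "errors") <- errors
  good
}

#' @rdname read_points
#' @param points data.frame of points.
#' @export
write_points <- function(points, path) {
  utils::write.csv(points[, point_columns(), drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read / write long-format NDVI tables
#'
#' Long CSV with columns \code{point_id}, \code{year}, \code{ndvi}.
#'
#' @param path CSV path.
#' @export
read_ndvi <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("point_id", "year", "ndvi"), names(d))
  if (length(miss))
    stop("NDVI table is missing required column(s): ",
         paste(miss, collapse = ", "))
  d
}

#' @rdname read_ndvi
#' @param ndvi long-format NDVI data.frame.
#' @export
write_ndvi <- function(ndvi, path) {
  utils::write.csv(ndvi[, c("point_id", "year", "ndvi")], path,
                   row.names = FALSE)
  invisible(path)
}
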