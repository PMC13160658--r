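#' Fit the full climate-sensitivity model to a point table
#'
#' The end-to-end estimator. From a table of forest-upper-limit location
#' points it:
#' \enumerate{
#'   \item fits the per-site height regression and derives normalized
#'     factor weights ([build_weight_matrix()]);
#'   \item runs the backward cloud generator over site weights within
#'     each mountain, per factor ([weight_clouds()]), and over point
#'     elevations ([height_cloud()]);
#'   \item converts the climate-factor weight digests and point shares
#'     into TSI, PSI and CSI with contribution rates and dominance
#'     labels ([sensitivity_records()]);
#'   \item aggregates by region and moisture class where labels are
#'     available, and fits the index-versus-latitude trend;
#'   \item optionally validates the indices against per-mountain mean
#'     absolute NDVI change rates ([validate_ndvi()]).
#' }
#'
#' @param points data.frame of location points (columns of
#'   [read_points()]).
#' @param ndvi optional long-format NDVI data.frame
#'   (\code{point_id}, \code{year}, \code{ndvi}).
#' @param mountain_meta optional data.frame with \code{mountain_id} and
#'   any of \code{region}, \code{moisture} labels.
#' @param factors factor column names.
#' @param scale index presentation scale (default 100).
#' @param N comparison-universe size; defaults to the total point count
#'   of \code{points}.
#' @return object of class \code{"ulmdb_sensitivity"} with components
#'   \code{records}, \code{weight_digests}, \code{height_digests},
#'   \code{weights}, \code{exclusions}, \code{regional},
#'   \code{by_moisture}, \code{latitude_trend}, \code{validation},
#'   \code{N}, \code{scale}, \code{call}.
#' @examples
#' study <- generate_study(default_study_config(
#'   n_mountains = 4, n_sites = 12, n_points = 360, n_arid = 1), seed = 7)
#' fit <- ulmdb_sensitivity(study$points, ndvi = study$ndvi)
#' fit
#' @export
ulmdb_sensitivity <- function(points, ndvi = NULL, mountain_meta = NULL,
                              factors = impact_factors(), scale = 100,
                              N = NULL) {
  cl <- match.call()
  wm <- build_weight_matrix(points, factors)
  digests <- weight_clouds(wm$weights, wm$mountain_ids)
  mts <- unique(as.character(points$mountain_id))
  pc_tab <- table(points$mountain_id)
  point_counts <- stats::setNames(as.integer(pc_tab), names(pc_tab))
  if (is.null(N)) N <- sum(point_counts)
  hts <- do.call(rbind, lapply(mts, function(m) {
    d <- height_cloud(points[points$mountain_id == m, ])
    cbind(data.frame(mountain_id = m, stringsAsFactors = FALSE),
          as.data.frame(d))
  }))
  coord <- do.call(rbind, lapply(mts, function(m) {
    p <- points[points$mountain_id == m, ]
    data.frame(mountain_id = m, latitude = mean(p$lat),
               longitude = mean(p$lon), stringsAsFactors = FALSE)
  }))
  meta <- coord
  if (!is.null(mountain_meta)) {
    keep <- intersect(c("mountain_id", "region", "moisture"),
                      names(mountain_meta))
    meta <- merge(meta, mountain_meta[, keep, drop = FALSE],
                  by = "mountain_id", all.x = TRUE, sort = FALSE)
  }
  records <- sensitivity_records(digests, point_counts, N = N,
                                 meta = meta, scale = scale)
  regional <- if ("region" %in% names(records) &&
                  !all(is.na(records$region)))
    regional_summary(records, "region") else NULL
  by_moisture <- if ("moisture" %in% names(records) &&
                     !all(is.na(records$moisture)))
    regional_summary(records, "moisture") else NULL
  lat_trend <- if (nrow(records) >= 3L)
    tryCatch(trend_vs_coordinate(records$csi, records$latitude),
             error = function(e) NULL) else NULL
  validation <- NULL
  responses <- NULL
  if (!is.null(ndvi)) {
    p2m <- stats::setNames(as.character(points$mountain_id),
                           points$point_id)
    ndvi$mountain_id <- p2m[as.character(ndvi$point_id)]
    responses <- vapply(mts, function(m)
      unit_ndvi_response(ndvi[ndvi$mountain_id == m,
                              c("point_id", "year", "ndvi")]),
      numeric(1))
    names(responses) <- mts
    validation <- validate_ndvi(records, responses)
  }
  structure(list(records = records, weight_digests = digests,
                 height_digests = hts, weights = wm$weights,
                 fits = wm$fits, exclusions = wm$exclusions,
                 regional = regional, by_moisture = by_moisture,
                 latitude_trend = lat_trend, validation = validation,
                 ndvi_responses = responses,
                 N = N, scale = scale, call = cl),
            class = "ulmdb_sensitivity")
}

#' @export
print.ulmdb_sensitivity <- function(x, ...) {
  cat("Cloud-model climate-sensitivity fit\n")
  cat(sprintf("  %d mountains, %d fitted sites (%d excluded), N = %d points\n",
              nrow(x$records), ncol(x$weights), nrow(x$exclusions), x$N))
  dom <- table(x$records$dominance)
  cat("  dominance:",
      paste(sprintf("%s %d", names(dom), dom), collapse = ", "), "\n")
  if (!is.null(x$validation))
    cat(sprintf("  NDVI validation: CSI rho = %.3f%s\n",
                x$validation$rho[x$validation$index == "comprehensive"],
                x$validation$signif[x$validation$index == "comprehensive"]))
  invisible(x)
}

#' @export
summary.ulmdb_sensitivity <- function(object, ...) {
  structure(list(fit = object), class = "summary.ulmdb_sensitivity")
}

#' @export
print.summary.ulmdb_sensitivity <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPer-mountain sensitivity indices (x", f$scale, "):\n", sep = "")
  r <- f$records
  r$p_temp <- sprintf("%.2f%%", 100 * r$p_temp)
  r$p_precip <- sprintf("%.2f%%", 100 * r$p_precip)
  num <- intersect(c("tsi", "psi", "csi"), names(r))
  r[num] <- lapply(r[num], round, 3)
  print(r, row.names = FALSE)
  if (!is.null(f$regional)) {
    cat("\nRegional means:\n")
    print(cbind(f$regional[1:2],
                round(f$regional[3:5], 3),
                f$regional[6:7]), row.names = FALSE)
  }
  if (!is.null(f$validation)) {
    cat("\nNDVI validation (Spearman):\n")
    v <- f$validation
    v$rho <- round(v$rho, 3)
    v$p_value <- signif(v$p_value, 3)
    print(v, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.ulmdb_sensitivity <- function(object, ...) object$weights

#' Plot method: cloud diagram or latitudinal pattern
#'
#' \code{type = "cloud"} draws the forward-cloud droplet diagram of each
#' mountain's distributed-height digest (droplet value vs. membership
#' degree). \code{type = "latitude"} plots CSI against mean latitude
#' with the fitted trend line.
#'
#' @param x an \code{ulmdb_sensitivity} fit.
#' @param type \code{"cloud"} or \code{"latitude"}.
#' @param n_droplets droplets per mountain for the cloud diagram.
#' @param seed seed for droplet generation.
#' @param ... passed to the underlying plot call.
#' @export
plot.ulmdb_sensitivity <- function(x, type = c("cloud", "latitude"),
                                   n_droplets = 500, seed = 1, ...) {
  type <- match.arg(type)
  if (type == "latitude") {
    graphics::plot(x$records$latitude, x$records$csi,
                   xlab = "Mean latitude (deg N)",
                   ylab = sprintf("CSI (x%g)", x$scale),
                   pch = 19, ...)
    if (!is.null(x$latitude_trend) && x$latitude_trend$ok)
      graphics::abline(x$latitude_trend$intercept, x$latitude_trend$slope,
                       col = "red")
    return(invisible(x))
  }
  hd <- x$height_digests
  cols <- grDevices::hcl.colors(nrow(hd), "Dark 3")
  first <- TRUE
  for (k in seq_len(nrow(hd))) {
    d <- forward_cloud(cloud(hd$Ex[k], hd$En[k], hd$He[k]),
                       n_droplets, seed = derive_seed(seed, k))
    if (first) {
      graphics::plot(d$x, d$membership, col = cols[k], pch = ".",
                     xlim = range(hd$Ex) + c(-4, 4) * max(hd$En),
                     ylim = c(0, 1), xlab = "Elevation (m)",
                     ylab = "Membership degree", ...)
      first <- FALSE
    } else graphics::points(d$x, d$membership, col = cols[k], pch = ".")
  }
  invisible(x)
}

#' Run the full pipeline and write its outputs
#'
#' Orchestrates simulate/ingest, weight fitting, cloud digestion,
#' sensitivity indices and NDVI validation, writing every declared
#' output under \code{out_dir}: the point table (when simulated), the
#' weight matrix and exclusions, the digest table, the per-mountain
#' sensitivity table, regional summaries (JSON), the validation table,
#' a resolved-config snapshot (JSON) and a markdown report.
#'
#' \code{config} is a list with either \code{points_csv} (+ optional
#' \code{ndvi_csv}) to ingest, or \code{study} (a
#' [default_study_config()]) to simulate, or \code{indices_csv} /
#' \code{indices} (a data.frame) carrying precomputed per-mountain
#' \code{tsi}/\code{psi} pairs to push through the index arithmetic
#' alone. Unknown config keys are rejected.
#'
#' @param config configuration list (see Details).
#' @param out_dir output directory (created if needed).
#' @param seed master seed for simulation.
#' @return invisibly, the result bundle: the fit (or records), file
#'   paths, and the resolved config.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("ulmdb_run_"),
                         seed = 1) {
  known <- c("points_csv", "ndvi_csv", "study", "indices_csv", "indices",
             "scale", "N", "mountain_meta")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  scale <- if (is.null(config$scale)) 100 else config$scale
  resolved <- list(seed = as.integer(seed), scale = scale,
                   out_dir = out_dir)

  if (!is.null(config$indices_csv) || !is.null(config$indices)) {
    tbl <- if (!is.null(config$indices)) config$indices else
      utils::read.csv(config$indices_csv, stringsAsFactors = FALSE)
    records <- sensitivity_from_indices(tbl)
    paths$sensitivity <- file.path(out_dir, "sensitivity.csv")
    write_sensitivity_csv(records, paths$sensitivity)
    bundle <- list(records = records, paths = paths,
                   resolved_config = c(resolved, mode = "indices"))
    if ("region" %in% names(records)) {
      bundle$regional <- regional_summary(records, "region")
      paths$regional <- file.path(out_dir, "regional_summary.json")
      jsonlite::write_json(bundle$regional, paths$regional,
                           dataframe = "rows", digits = NA)
      bundle$paths <- paths
    }
    writeLines(render_report(bundle), file.path(out_dir, "report.md"))
    jsonlite::write_json(bundle$resolved_config,
                         file.path(out_dir, "config_snapshot.json"),
                         auto_unbox = TRUE)
    return(invisible(bundle))
  }

  if (!is.null(config$points_csv)) {
    points <- read_points(config$points_csv)
    ndvi <- if (!is.null(config$ndvi_csv)) read_ndvi(config$ndvi_csv)
    resolved$mode <- "ingest"
    mountain_meta <- config$mountain_meta
  } else {
    study_cfg <- if (is.null(config$study)) default_study_config()
                 else config$study
    study <- generate_study(study_cfg, seed = seed)
    points <- study$points
    ndvi <- study$ndvi
    mountain_meta <- study$truth[, c("mountain_id", "region", "moisture")]
    resolved$mode <- "simulate"
    paths$points <- file.path(out_dir, "points.csv")
    write_points(points, paths$points)
    paths$ndvi <- file.path(out_dir, "ndvi.csv")
    write_ndvi(ndvi, paths$ndvi)
  }

  fit <- ulmdb_sensitivity(points, ndvi = ndvi,
                           mountain_meta = mountain_meta,
                           scale = scale, N = config$N)

  paths$weights <- file.path(out_dir, "weights.csv")
  utils::write.csv(fit$weights, paths$weights, row.names = TRUE)
  paths$exclusions <- file.path(out_dir, "exclusions.csv")
  utils::write.csv(fit$exclusions, paths$exclusions, row.names = FALSE)
  paths$digests <- file.path(out_dir, "digests.csv")
  utils::write.csv(fit$weight_digests, paths$digests, row.names = FALSE)
  paths$sensitivity <- file.path(out_dir, "sensitivity.csv")
  write_sensitivity_csv(fit$records, paths$sensitivity)
  if (!is.null(fit$regional)) {
    paths$regional <- file.path(out_dir, "regional_summary.json")
    jsonlite::write_json(fit$regional, paths$regional,
                         dataframe = "rows", digits = NA)
  }
  if (!is.null(fit$validation)) {
    paths$validation <- file.path(out_dir, "validation.csv")
    utils::write.csv(fit$validation, paths$validation, row.names = FALSE)
  }
  jsonlite::write_json(resolved, file.path(out_dir, "config_snapshot.json"),
                       auto_unbox = TRUE)
  bundle <- list(fit = fit, records = fit$records, paths = paths,
                 resolved_config = resolved)
  writeLines(render_report(bundle), file.path(out_dir, "report.md"))
  invisible(bundle)
}

# sensitivity table writer: percentages to 2 decimals alongside raw values
write_sensitivity_csv <- function(records, path) {
  out <- records
  out$p_temp_pct <- sprintf("%.2f", 100 * out$p_temp)
  out$p_precip_pct <- sprintf("%.2f", 100 * out$p_precip)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Render a markdown report from a pipeline bundle
#'
#' Per-mountain sensitivity table, regional means and dominance counts,
#' and the NDVI validation table; sections whose inputs are absent are
#' marked explicitly rather than omitted.
#'
#' @param bundle result of [run_pipeline()] (or a list with
#'   \code{records} and optionally \code{regional}, \code{fit}).
#' @return character vector of markdown lines.
#' @export
render_report <- function(bundle) {
  r <- bundle$records
  lines <- c("# Climate-change sensitivity report", "",
             sprintf("%d mountains.", nrow(r)), "",
             "## Per-mountain indices", "",
             "| Mountain | TSI | PSI | CSI | P_temp | P_precip | Dominance |",
             "|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(r))) {
    lines <- c(lines, sprintf(
      "| %s | %.3f | %.3f | %.3f | %.2f%% | %.2f%% | %s |",
      r$mountain_id[i], r$tsi[i], r$psi[i], r$csi[i],
      100 * r$p_temp[i], 100 * r$p_precip[i], r$dominance[i]))
  }
  lines <- c(lines, "", "## Regional summary", "")
  reg <- bundle$regional
  if (is.null(reg) && !is.null(bundle$fit)) reg <- bundle$fit$regional
  if (is.null(reg)) {
    lines <- c(lines, "_No regional labels available._")
  } else {
    lines <- c(lines,
               "| Region | n | mean TSI | mean PSI | mean CSI | T-dom | P-dom |",
               "|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(reg))) {
      lines <- c(lines, sprintf(
        "| %s | %d | %.3f | %.3f | %.3f | %d | %d |",
        reg[[1]][i], reg$n_mountains[i], reg$mean_tsi[i],
        reg$mean_psi[i], reg$mean_csi[i], reg$n_temp_dominated[i],
        reg$n_precip_dominated[i]))
    }
  }
  lines <- c(lines, "", "## NDVI validation", "")
  val <- if (!is.null(bundle$fit)) bundle$fit$validation
  if (is.null(val)) {
    lines <- c(lines, "_Validation section absent (no NDVI input)._")
  } else {
    lines <- c(lines, "| Index | Spearman rho | p | |", "|---|---|---|---|")
    for (i in seq_len(nrow(val))) {
      lines <- c(lines, sprintf("| %s | %.3f | %.3g | %s |",
                                val$index[i], val$rho[i], val$p_value[i],
                                val$signif[i]))
    }
  }
  lines
}
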