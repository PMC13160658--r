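#' Single-factor climate sensitivity index
#'
#' For a climate factor's weight-cloud digest in one mountain,
#' \deqn{SI = \frac{Ex}{En + He} \times \frac{N_i}{N} \times scale,}
#' where \eqn{N_i} is the mountain's location-point count and \eqn{N} the
#' total across the comparison universe (the whole study by default). A
#' high expected weight with low entropy and hyperentropy — a strong,
#' stable, spatially homogeneous influence — yields a high index. The
#' point-share term corrects for unequal sampling across mountains so
#' indices are comparable between regions.
#'
#' When \code{En + He = 0} (a degenerate, perfectly crisp weight cloud)
#' the default policy floors the denominator at \code{eps} with a
#' warning; \code{zero_policy = "infinite"} returns \code{Inf} instead so
#' callers can flag the mountain.
#'
#' @param digest a [cloud()] digest of the factor's weight.
#' @param Ni number of location points in the mountain.
#' @param N total number of location points in the comparison universe.
#' @param scale output multiplier (default 100, the conventional
#'   presentation scale).
#' @param zero_policy \code{"epsilon"} (default) or \code{"infinite"}.
#' @param eps denominator floor under the epsilon policy.
#' @return the sensitivity index (unitless, already multiplied by
#'   \code{scale}).
#' @export
single_factor_si <- function(digest, Ni, N, scale = 100,
                             zero_policy = c("epsilon", "infinite"),
                             eps = 1e-6) {
  stopifnot(inherits(digest, "cloud"), Ni >= 0, N > 0, Ni <= N)
  zero_policy <- match.arg(zero_policy)
  if (Ni == 0) return(0)
  denom <- digest$En + digest$He
  if (denom == 0) {
    if (zero_policy == "infinite") return(Inf)
    warning("En + He = 0; denominator floored at ", eps)
    denom <- eps
  }
  digest$Ex / denom * (Ni / N) * scale
}

#' Comprehensive sensitivity index
#'
#' The sum of the single-factor sensitivity indices of the climate
#' factors (temperature and precipitation), all sharing the same
#' point-share and scale. With two climate factors, CSI = TSI + PSI.
#'
#' @param climate_sis numeric vector of single-factor indices (already on
#'   the common scale).
#' @return their sum.
#' @export
comprehensive_csi <- function(climate_sis) {
  if (length(climate_sis) < 1L) stop("need at least one climate-factor SI")
  sum(climate_sis)
}

#' Contribution rate of a single-factor index
#'
#' \eqn{P_i = SI_i / CSI_i}: the share of the comprehensive index carried
#' by one climate factor. A contribution rate strictly above 50% marks
#' the mountain as dominated by that factor.
#'
#' @param SI single-factor sensitivity index.
#' @param CSI comprehensive sensitivity index (> 0).
#' @return contribution rate in [0, 1].
#' @export
contribution_rate <- function(SI, CSI) {
  if (!is.finite(CSI) || CSI <= 0)
    stop("contribution rate undefined: CSI must be finite and > 0")
  SI / CSI
}

#' Dominance classification from contribution rates
#'
#' \code{"temperature"} when the temperature contribution exceeds 0.5,
#' \code{"precipitation"} when the precipitation contribution exceeds
#' 0.5, and \code{"mixed"} at exactly 0.5 (the strict inequality is the
#' documented tie rule).
#'
#' @param p_temp temperature contribution rate in [0, 1].
#' @param p_precip precipitation contribution rate; defaults to
#'   \code{1 - p_temp}.
#' @return character label.
#' @export
classify_dominance <- function(p_temp, p_precip = 1 - p_temp) {
  stopifnot(is.finite(p_temp), is.finite(p_precip))
  if (p_temp > 0.5) "temperature"
  else if (p_precip > 0.5) "precipitation"
  else "mixed"
}

#' Per-mountain sensitivity records from weight clouds
#'
#' Combines the per-mountain, per-factor weight-cloud digests with the
#' mountains' point counts into the sensitivity table: TSI, PSI, CSI,
#' contribution rates and dominance labels per mountain.
#'
#' @param digests data.frame from [weight_clouds()].
#' @param point_counts named vector: location points per mountain
#'   (names = mountain ids).
#' @param N total points of the comparison universe; default
#'   \code{sum(point_counts)}.
#' @param meta optional data.frame with \code{mountain_id} plus any of
#'   \code{latitude}, \code{longitude}, \code{region}, \code{moisture}
#'   to carry through.
#' @param scale output multiplier (default 100).
#' @param temp_factor,precip_factor names of the climate factors in
#'   \code{digests$factor}.
#' @return data.frame with one row per mountain: \code{mountain_id},
#'   \code{tsi}, \code{psi}, \code{csi}, \code{p_temp}, \code{p_precip},
#'   \code{dominance}, \code{n_points}, plus any metadata columns.
#' @export
sensitivity_records <- function(digests, point_counts,
                                N = sum(point_counts), meta = NULL,
                                scale = 100,
                                temp_factor = "jan_temp_c",
                                precip_factor = "annual_precip_mm") {
  stopifnot(is.data.frame(digests),
            all(c("mountain_id", "factor", "Ex", "En", "He") %in%
                names(digests)))
  mts <- unique(digests$mountain_id)
  rows <- lapply(mts, function(m) {
    Ni <- point_counts[[as.character(m)]]
    if (is.null(Ni) || is.na(Ni))
      stop("no point count for mountain ", m)
    one <- function(f) {
      r <- digests[digests$mountain_id == m & digests$factor == f, ]
      if (nrow(r) != 1L) stop("missing digest for ", m, " / ", f)
      single_factor_si(cloud(r$Ex, r$En, r$He, n = r$n), Ni, N, scale)
    }
    tsi <- one(temp_factor)
    psi <- one(precip_factor)
    csi <- comprehensive_csi(c(tsi, psi))
    p_t <- contribution_rate(tsi, csi)
    p_p <- contribution_rate(psi, csi)
    data.frame(mountain_id = as.character(m), tsi = tsi, psi = psi,
               csi = csi, p_temp = p_t, p_precip = p_p,
               dominance = classify_dominance(p_t, p_p),
               n_points = Ni, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(meta)) {
    keep <- intersect(c("mountain_id", "latitude", "longitude", "region",
                        "moisture"), names(meta))
    out <- merge(out, meta[, keep, drop = FALSE], by = "mountain_id",
                 sort = FALSE)
  }
  out
}

#' Sensitivity records from precomputed single-factor indices
#'
#' Entry point for tables that already carry per-mountain temperature and
#' precipitation indices (e.g. published summaries): recomputes CSI,
#' contribution rates and dominance from the index pair alone.
#'
#' @param tbl data.frame with \code{mountain_id} (or \code{mountain}),
#'   \code{tsi}, \code{psi} and optional metadata columns
#'   (\code{latitude}, \code{longitude}, \code{region}, \code{moisture}).
#' @return data.frame as in [sensitivity_records()] (without
#'   \code{n_points}).
#' @export
sensitivity_from_indices <- function(tbl) {
  if ("mountain" %in% names(tbl) && !"mountain_id" %in% names(tbl))
    names(tbl)[names(tbl) == "mountain"] <- "mountain_id"
  stopifnot(all(c("mountain_id", "tsi", "psi") %in% names(tbl)))
  csi <- tbl$tsi + tbl$psi
  p_t <- mapply(contribution_rate, tbl$tsi, csi)
  p_p <- mapply(contribution_rate, tbl$psi, csi)
  out <- data.frame(mountain_id = as.character(tbl$mountain_id),
                    tsi = tbl$tsi, psi = tbl$psi, csi = csi,
                    p_temp = p_t, p_precip = p_p,
                    dominance = mapply(classify_dominance, p_t, p_p),
                    stringsAsFactors = FALSE)
  for (col in intersect(c("latitude", "longitude", "region", "moisture"),
                        names(tbl)))
    out[[col]] <- tbl[[col]]
  out
}

#' Regional aggregation of sensitivity records
#'
#' Per group (study region or moisture class): mean TSI/PSI/CSI, the
#' counts and fractions of temperature-dominated (P_temp > 0.5) and
#' precipitation-dominated (P_precip > 0.5) mountains.
#'
#' @param records data.frame from [sensitivity_records()] or
#'   [sensitivity_from_indices()].
#' @param grouping name of the grouping column (\code{"region"} or
#'   \code{"moisture"}).
#' @return data.frame: one row per group with \code{n_mountains},
#'   \code{mean_tsi}, \code{mean_psi}, \code{mean_csi},
#'   \code{n_temp_dominated}, \code{n_precip_dominated},
#'   \code{frac_temp_dominated}, \code{frac_precip_dominated}.
#' @export
regional_summary <- function(records, grouping = "region") {
  if (!grouping %in% names(records))
    stop("grouping column '", grouping, "' not present")
  g <- records[[grouping]]
  empty <- is.na(g) | g == ""
  if (any(empty)) {
    warning(sum(empty), " record(s) without a '", grouping,
            "' label omitted")
    records <- records[!empty, , drop = FALSE]
    g <- records[[grouping]]
  }
  rows <- lapply(unique(g), function(grp) {
    r <- records[g == grp, , drop = FALSE]
    nt <- sum(r$p_temp > 0.5)
    np <- sum(r$p_precip > 0.5)
    data.frame(group = grp, n_mountains = nrow(r),
               mean_tsi = mean(r$tsi), mean_psi = mean(r$psi),
               mean_csi = mean(r$csi),
               n_temp_dominated = nt, n_precip_dominated = np,
               frac_temp_dominated = nt / nrow(r),
               frac_precip_dominated = np / nrow(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- grouping
  out
}

#' Linear trend of a per-mountain quantity against a coordinate
#'
#' Simple least-squares line of a value (e.g. the height-cloud Ex or the
#' CSI) on latitude or longitude, with Pearson r, R^2 and a two-sided
#' p-value — the spatial-pattern fits of the analysis.
#'
#' @param values numeric response, one per mountain.
#' @param coordinate numeric predictor (latitude or longitude), same
#'   length, n >= 3.
#' @return object of class \code{"trend_fit"}: \code{slope},
#'   \code{intercept}, \code{r}, \code{r_squared}, \code{p_value},
#'   \code{n}, \code{ok}, \code{reason}.
#' @export
trend_vs_coordinate <- function(values, coordinate) {
  stopifnot(length(values) == length(coordinate))
  ok <- is.finite(values) & is.finite(coordinate)
  x <- coordinate[ok]; y <- values[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  flagged <- function(reason) structure(
    list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
         r_squared = NA_real_, p_value = NA_real_, n = n, ok = FALSE,
         reason = reason), class = "trend_fit")
  if (stats::sd(x) == 0) return(flagged("zero_coordinate_variance"))
  if (stats::sd(y) == 0) return(flagged("zero_value_variance"))
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
         p_value = ct$p.value, n = n, ok = TRUE, reason = ""),
    class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  if (!x$ok) {
    cat(sprintf("trend_fit: undefined (%s), n = %d\n", x$reason, x$n))
    return(invisible(x))
  }
  cat(sprintf(
    "trend_fit: slope = %.4g, intercept = %.4g, r = %.3f, R^2 = %.3f, p = %.3g (n = %d)\n",
    x$slope, x$intercept, x$r, x$r_squared, x$p_value, x$n))
  invisible(x)
}
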