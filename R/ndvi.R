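#' NDVI change rate of one series
#'
#' Ordinary least-squares slope of annual NDVI on the year index
#' i = 1..n: the per-point greening/browning rate in NDVI units per
#' year. Closed form:
#' \deqn{slope = \frac{n\sum_i i\,NDVI_i - \sum_i i \sum_i NDVI_i}
#'                    {n\sum_i i^2 - (\sum_i i)^2}.}
#'
#' @param ndvi numeric vector of annual NDVI values (year index
#'   implicit), length >= 2.
#' @return slope in NDVI per year.
#' @export
ndvi_slope <- function(ndvi) {
  ndvi <- as.numeric(ndvi)
  if (anyNA(ndvi) || !all(is.finite(ndvi)))
    stop("NDVI series must be finite and free of NA")
  n <- length(ndvi)
  if (n < 2L) stop("NDVI series needs at least 2 years")
  i <- seq_len(n)
  (n * sum(i * ndvi) - sum(i) * sum(ndvi)) /
    (n * sum(i^2) - sum(i)^2)
}

#' Mean absolute NDVI response of an analysis unit
#'
#' The arithmetic mean of the absolute NDVI change rates over all
#' location points of a mountain; larger values indicate a stronger
#' vegetation response to climate change regardless of direction.
#'
#' @param series list of numeric NDVI series (one per point), or a
#'   long-format data.frame with \code{point_id}, \code{year},
#'   \code{ndvi} columns.
#' @return mean absolute slope (>= 0).
#' @export
unit_ndvi_response <- function(series) {
  if (is.data.frame(series)) {
    stopifnot(all(c("point_id", "year", "ndvi") %in% names(series)))
    series <- lapply(split(series, series$point_id), function(d)
      d$ndvi[order(d$year)])
  }
  if (length(series) == 0L) stop("no NDVI series supplied")
  mean(vapply(series, function(s) abs(ndvi_slope(s)), numeric(1)))
}

#' Spearman rank correlation with tie-corrected average ranks
#'
#' rho is the Pearson correlation of the average ranks (the tie-safe
#' definition). The two-sided p-value uses the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} by default; for n <= 8 an exact
#' permutation p (full enumeration of all n! orderings, valid under
#' ties) is available.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param p_method \code{"t"} (default) or \code{"exact"} (n <= 8 only).
#' @return list with \code{rho}, \code{p_value}, \code{n}, \code{ok},
#'   \code{reason} (rank-degenerate inputs give \code{ok = FALSE}).
#' @export
spearman_rho <- function(x, y, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, ok = FALSE,
                reason = "zero_rank_variance"))
  rho <- stats::cor(rx, ry)
  if (p_method == "exact") {
    if (n > 8L) stop("exact permutation p only supported for n <= 8")
    perms <- permutations_of(n)
    obs <- abs(rho)
    cnt <- 0L
    for (k in seq_len(nrow(perms))) {
      r <- stats::cor(rx, ry[perms[k, ]])
      if (abs(r) >= obs - 1e-12) cnt <- cnt + 1L
    }
    p <- cnt / nrow(perms)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p_value = p, n = n, ok = TRUE, reason = "")
}

# all permutations of 1..n as rows (n small)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1L
  for (pos in seq_len(n)) {
    for (k in seq_len(nrow(sub))) {
      row <- append(sub[k, ], n, after = pos - 1L)
      out[r, ] <- row
      r <- r + 1L
    }
  }
  out
}

#' Validate sensitivity indices against NDVI responses
#'
#' Spearman correlation of each sensitivity index (TSI, PSI, CSI) with
#' the per-mountain mean absolute NDVI change rate, with significance
#' stars at the 0.05 (*) and 0.01 (**) levels.
#'
#' @param records data.frame from [sensitivity_records()] (columns
#'   \code{mountain_id}, \code{tsi}, \code{psi}, \code{csi}).
#' @param responses named numeric vector of per-mountain NDVI responses
#'   (names = mountain ids), or a data.frame with \code{mountain_id} and
#'   \code{response}.
#' @param p_method passed to [spearman_rho()].
#' @return data.frame with one row per index (\code{temperature},
#'   \code{precipitation}, \code{comprehensive}): \code{rho},
#'   \code{p_value}, \code{n}, \code{signif}.
#' @export
validate_ndvi <- function(records, responses, p_method = "t") {
  if (is.data.frame(responses)) {
    stopifnot(all(c("mountain_id", "response") %in% names(responses)))
    responses <- stats::setNames(responses$response,
                                 responses$mountain_id)
  }
  common <- intersect(records$mountain_id, names(responses))
  missing_m <- setdiff(records$mountain_id, names(responses))
  if (length(common) < 3L)
    stop("fewer than 3 mountains with both index and NDVI response; ",
         "missing responses for: ",
         paste(missing_m, collapse = ", "))
  r <- records[match(common, records$mountain_id), ]
  resp <- responses[common]
  one <- function(v) spearman_rho(v, resp, p_method = p_method)
  res <- list(temperature = one(r$tsi), precipitation = one(r$psi),
              comprehensive = one(r$csi))
  stars <- function(p) if (!is.finite(p)) "" else if (p < 0.01) "**"
                       else if (p < 0.05) "*" else ""
  data.frame(
    index = names(res),
    rho = vapply(res, `[[`, numeric(1), "rho"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    n = vapply(res, `[[`, integer(1), "n"),
    signif = vapply(res, function(z) stars(z$p_value), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
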