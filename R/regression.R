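#' The five impact-factor column names used throughout the package
#' @export
impact_factors <- function() {
  c("aspect_class", "relief_m", "mountaintop_m2", "jan_temp_c",
    "annual_precip_mm")
}

# factors flagged as climatic (temperature, precipitation)
climate_factors <- function() c("jan_temp_c", "annual_precip_mm")

#' Fit the per-site distributed-height model
#'
#' Ordinary least squares of point elevation on the five impact factors
#' within one analysis unit (a ULMDB site):
#' \deqn{y = a_1 x_1 + a_2 x_2 + \dots + a_5 x_5 + b + \varepsilon.}
#' The aspect class enters as a numeric 1-4 covariate (the reclassified
#' value is regressed directly, not dummy-coded). Standardized
#' coefficients are the raw coefficients scaled by
#' \code{sd(factor) / sd(elevation)}; they are unitless and their
#' magnitudes feed the factor weights.
#'
#' A unit is fittable when it holds at least \code{length(factors) + 2}
#' complete points, the response varies, and the design has full column
#' rank; otherwise the fit is flagged (\code{ok = FALSE}) with a reason
#' and the unit is later excluded from the weight matrix.
#'
#' @param unit data.frame of the unit's points with \code{elevation_m}
#'   and the factor columns.
#' @param factors character vector of factor column names.
#' @return object of class \code{"height_fit"}: raw coefficients
#'   \code{coef}, intercept \code{b}, standardized coefficients
#'   \code{std_coef}, \code{r_squared}, \code{n}, \code{ok},
#'   \code{reason}.
#' @export
fit_height_model <- function(unit, factors = impact_factors()) {
  cols <- c("elevation_m", factors)
  missing_cols <- setdiff(cols, names(unit))
  if (length(missing_cols))
    stop("unit is missing columns: ", paste(missing_cols, collapse = ", "))
  dat <- unit[stats::complete.cases(unit[, cols]), cols, drop = FALSE]
  n <- nrow(dat)
  bad <- function(reason) structure(
    list(coef = stats::setNames(rep(NA_real_, length(factors)), factors),
         b = NA_real_, std_coef = stats::setNames(rep(NA_real_,
             length(factors)), factors),
         r_squared = NA_real_, n = n, ok = FALSE, reason = reason),
    class = "height_fit")
  if (n < length(factors) + 2L) return(bad("too_few_points"))
  sy <- stats::sd(dat$elevation_m)
  if (!is.finite(sy) || sy == 0) return(bad("constant_response"))
  fm <- stats::as.formula(paste("elevation_m ~",
                                paste(factors, collapse = " + ")))
  fit <- stats::lm(fm, data = dat)
  if (fit$rank < length(factors) + 1L || anyNA(stats::coef(fit)))
    return(bad("rank_deficient"))
  cf <- stats::coef(fit)
  a <- cf[factors]
  sx <- vapply(dat[factors], stats::sd, numeric(1))
  std <- a * sx / sy
  r2 <- summary(fit)$r.squared
  structure(
    list(coef = a, b = unname(cf["(Intercept)"]), std_coef = std,
         r_squared = r2, n = n, ok = TRUE, reason = ""),
    class = "height_fit")
}

#' @export
print.height_fit <- function(x, ...) {
  if (!x$ok) {
    cat(sprintf("height_fit: NOT fittable (%s), n = %d\n", x$reason, x$n))
    return(invisible(x))
  }
  cat(sprintf("height_fit: n = %d, R^2 = %.4f, intercept = %.2f m\n",
              x$n, x$r_squared, x$b))
  print(round(rbind(raw = x$coef, standardized = x$std_coef), 4))
  invisible(x)
}

#' Normalized factor weights from a fitted height model
#'
#' The relative importance of factor i is the magnitude of its
#' standardized coefficient, normalized so the five weights sum to 1:
#' \deqn{w_i = |\beta_i| / \sum_j |\beta_j|.}
#' The signs are kept in the fit object for diagnostics but never enter
#' the weights.
#'
#' @param fit a [fit_height_model()] result.
#' @return named numeric weight vector (sums to 1), or \code{NULL} with
#'   attribute handling when all standardized coefficients vanish.
#' @export
weights_from_fit <- function(fit) {
  stopifnot(inherits(fit, "height_fit"))
  if (!fit$ok) stop("cannot derive weights from an unfittable unit (",
                    fit$reason, ")")
  ab <- abs(fit$std_coef)
  tot <- sum(ab)
  if (tot == 0) stop("all standardized coefficients are zero")
  ab / tot
}

#' Build the weight matrix over all analysis units
#'
#' Fits the height model per site and assembles the per-site weight
#' vectors as columns (rows = factors). Unfittable sites are excluded and
#' listed, with reasons, in the \code{exclusions} companion so nothing is
#' silently dropped.
#'
#' @param points data.frame of location points with \code{site_id},
#'   \code{mountain_id}, \code{elevation_m} and factor columns.
#' @param factors factor column names.
#' @return list with \code{weights} (matrix, rows = factors, columns
#'   named by site), \code{mountain_ids} (per column), \code{fits}
#'   (per-site \code{height_fit}s), and \code{exclusions} (data.frame
#'   site_id, mountain_id, reason).
#' @export
build_weight_matrix <- function(points, factors = impact_factors()) {
  stopifnot(all(c("site_id", "mountain_id") %in% names(points)))
  sites <- unique(points$site_id)
  W <- matrix(NA_real_, nrow = length(factors), ncol = 0,
              dimnames = list(factors, NULL))
  m_ids <- character(0)
  fits <- list()
  excl <- list()
  for (s in sites) {
    unit <- points[points$site_id == s, , drop = FALSE]
    mid <- as.character(unit$mountain_id[1])
    fit <- fit_height_model(unit, factors)
    fits[[as.character(s)]] <- fit
    w <- if (fit$ok) tryCatch(weights_from_fit(fit), error = function(e) NULL)
         else NULL
    if (is.null(w)) {
      reason <- if (fit$ok) "zero_standardized_coefficients" else fit$reason
      excl[[length(excl) + 1L]] <- data.frame(
        site_id = as.character(s), mountain_id = mid, reason = reason,
        stringsAsFactors = FALSE)
      next
    }
    W <- cbind(W, w)
    colnames(W)[ncol(W)] <- as.character(s)
    m_ids <- c(m_ids, mid)
  }
  if (ncol(W) == 0L) stop("no fittable analysis units")
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(site_id = character(0), mountain_id = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  list(weights = W, mountain_ids = m_ids, fits = fits,
       exclusions = exclusions)
}
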