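#' Construct a cloud digest
#'
#' A normal cloud represents a qualitative concept by three digital
#' features: the expectation \code{Ex} (centre of the concept, in the units
#' of the modelled quantity), the entropy \code{En} (>= 0, the fuzziness or
#' acceptable range of the concept), and the hyperentropy \code{He} (>= 0,
#' the dispersion of the entropy itself, i.e. second-order uncertainty).
#'
#' @param Ex expectation.
#' @param En entropy, must be >= 0.
#' @param He hyperentropy, must be >= 0.
#' @param n sample count behind the digest (NA for an a-priori digest).
#' @param low_confidence logical; marks digests estimated from fewer than
#'   two samples, where \code{En} and \code{He} are not identifiable.
#' @return an object of class \code{"cloud"}.
#' @seealso [backward_cloud()], [forward_cloud()]
#' @export
cloud <- function(Ex, En, He, n = NA_integer_, low_confidence = FALSE) {
  stopifnot(is.numeric(Ex), length(Ex) == 1L, is.finite(Ex))
  if (!is.finite(En) || En < 0) stop("'En' must be finite and >= 0")
  if (!is.finite(He) || He < 0) stop("'He' must be finite and >= 0")
  structure(
    list(Ex = as.numeric(Ex), En = as.numeric(En), He = as.numeric(He),
         n = as.integer(n), low_confidence = isTRUE(low_confidence)),
    class = "cloud"
  )
}

#' @export
print.cloud <- function(x, digits = 6, ...) {
  cat("Normal cloud digest", if (x$low_confidence) "(low confidence)", "\n")
  cat(sprintf("  Ex = %s  En = %s  He = %s",
              format(x$Ex, digits = digits),
              format(x$En, digits = digits),
              format(x$He, digits = digits)))
  if (!is.na(x$n)) cat(sprintf("   (n = %d)", x$n))
  cat("\n")
  invisible(x)
}

#' @export
format.cloud <- function(x, digits = 4, ...) {
  sprintf("cloud(Ex=%s, En=%s, He=%s)",
          format(x$Ex, digits = digits), format(x$En, digits = digits),
          format(x$He, digits = digits))
}

#' @export
as.data.frame.cloud <- function(x, ...) {
  data.frame(Ex = x$Ex, En = x$En, He = x$He, n = x$n,
             low_confidence = x$low_confidence)
}

#' Backward cloud generator: estimate (Ex, En, He) from samples
#'
#' The certainty-free moment estimator. With sample mean \eqn{\bar x},
#' \deqn{Ex = \bar x,\qquad
#'       En = \sqrt{\pi/2}\,\frac{1}{n}\sum_i |x_i - Ex|,\qquad
#'       He = \sqrt{|S^2 - En^2|},}
#' where \eqn{S^2} is the unbiased (n-1) sample variance. The absolute
#' value inside the root guards against \eqn{S^2 < En^2}, which occurs in
#' small samples; the divisor conventions (n for the mean absolute
#' deviation, n-1 for the variance) are fixed here because the literature
#' varies. The estimator lives behind this single function so a variant
#' can be swapped without touching callers.
#'
#' @param samples numeric vector, length >= 2, all finite.
#' @return a [cloud()] digest with \code{n = length(samples)}.
#' @examples
#' backward_cloud(c(1, 2, 3, 4, 5))
#' @export
backward_cloud <- function(samples) {
  samples <- as.numeric(samples)
  if (anyNA(samples) || !all(is.finite(samples)))
    stop("'samples' must be finite and free of NA")
  n <- length(samples)
  if (n == 0L) stop("no samples supplied")
  if (n == 1L) stop("a single sample cannot identify En and He (n = 1)")
  Ex <- mean(samples)
  En <- sqrt(pi / 2) * mean(abs(samples - Ex))
  S2 <- stats::var(samples)
  He <- sqrt(abs(S2 - En^2))
  cloud(Ex, En, He, n = n)
}

#' Forward cloud generator: draw droplets from a digest
#'
#' Each droplet draws a per-droplet entropy \eqn{En' \sim N(En, He^2)},
#' then a value \eqn{x \sim N(Ex, En'^2)}, and carries the membership
#' degree \eqn{\mu = \exp(-(x - Ex)^2 / (2 En'^2))}. A degenerate droplet
#' with \eqn{En' = 0} sits exactly at \code{Ex} with \eqn{\mu = 1}, so
#' membership always lies in (0, 1] and equals 1 iff \eqn{x = Ex}.
#'
#' @param digest a [cloud()] digest (or anything coercible via Ex/En/He
#'   fields).
#' @param n_droplets number of droplets, >= 1.
#' @param seed optional integer seed; when supplied the draw is
#'   reproducible and the seed is recorded on the result for replay.
#' @return data.frame with columns \code{x} and \code{membership}, one row
#'   per droplet; attribute \code{"seed"} records the seed used.
#' @examples
#' d <- forward_cloud(cloud(0.5, 0.1, 0.02), 1000, seed = 1)
#' range(d$membership)
#' @export
forward_cloud <- function(digest, n_droplets, seed = NULL) {
  if (!inherits(digest, "cloud")) stop("'digest' must be a cloud object")
  n_droplets <- as.integer(n_droplets)
  if (is.na(n_droplets) || n_droplets < 1L)
    stop("'n_droplets' must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  En_prime <- stats::rnorm(n_droplets, mean = digest$En, sd = digest$He)
  x <- stats::rnorm(n_droplets, mean = digest$Ex, sd = abs(En_prime))
  dev2 <- (x - digest$Ex)^2
  mu <- ifelse(En_prime == 0,
               as.numeric(dev2 == 0),
               exp(-dev2 / (2 * En_prime^2)))
  # En' == 0 forces x == Ex under rnorm(sd = 0), hence mu = 1 there
  out <- data.frame(x = x, membership = mu)
  attr(out, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  out
}

#' @describeIn forward_cloud \code{simulate()} method: draws
#'   \code{nsim} droplets from a cloud digest.
#' @param object a \code{cloud} digest (simulate method).
#' @param nsim number of droplets (simulate method).
#' @param ... unused.
#' @export
simulate.cloud <- function(object, nsim = 1, seed = NULL, ...) {
  forward_cloud(object, n_droplets = nsim, seed = seed)
}

#' Distributed-height cloud of one mountain
#'
#' Applies the backward cloud generator to the elevations of all location
#' points of a mountain, yielding the digest of the distributed height:
#' Ex is the expected upper-limit elevation, En its fuzziness/range, He
#' the dispersion of that range.
#'
#' @param points data.frame with an \code{elevation_m} column (or a bare
#'   numeric vector of elevations).
#' @return a [cloud()] digest in metres.
#' @export
height_cloud <- function(points) {
  elev <- if (is.data.frame(points)) {
    if (!"elevation_m" %in% names(points))
      stop("'points' must have an 'elevation_m' column")
    points$elevation_m
  } else as.numeric(points)
  backward_cloud(elev)
}

#' Per-mountain, per-factor weight-coefficient clouds
#'
#' Groups the columns of a weight matrix (rows = factors, columns = sites)
#' by mountain and runs the backward cloud generator over each factor's
#' site weights within each mountain. The result is the weight-coefficient
#' cloud model: one (Ex, En, He) triple per mountain x factor.
#'
#' Mountains contributing a single site cannot identify En/He; their
#' digests fall back to (value, 0, 0) and are flagged
#' \code{low_confidence}.
#'
#' @param weight_matrix numeric matrix, rows named by factor, columns are
#'   sites (as built by [build_weight_matrix()]).
#' @param mountain_ids vector of length \code{ncol(weight_matrix)} mapping
#'   each site column to its mountain.
#' @return data.frame with columns \code{mountain_id}, \code{factor},
#'   \code{Ex}, \code{En}, \code{He}, \code{n}, \code{low_confidence}.
#' @export
weight_clouds <- function(weight_matrix, mountain_ids) {
  if (!is.matrix(weight_matrix) || !is.numeric(weight_matrix))
    stop("'weight_matrix' must be a numeric matrix")
  if (length(mountain_ids) != ncol(weight_matrix))
    stop("'mountain_ids' must have one entry per weight-matrix column")
  if (is.null(rownames(weight_matrix)))
    rownames(weight_matrix) <- paste0("factor", seq_len(nrow(weight_matrix)))
  res <- list()
  for (m in unique(mountain_ids)) {
    cols <- which(mountain_ids == m)
    for (f in rownames(weight_matrix)) {
      w <- weight_matrix[f, cols]
      if (length(w) >= 2L) {
        d <- backward_cloud(w)
      } else {
        d <- cloud(w, 0, 0, n = 1L, low_confidence = TRUE)
      }
      res[[length(res) + 1L]] <- data.frame(
        mountain_id = m, factor = f, Ex = d$Ex, En = d$En, He = d$He,
        n = d$n, low_confidence = d$low_confidence,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
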