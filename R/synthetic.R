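#' Factor specification for the synthetic generator
#'
#' Describes how one impact factor is drawn: its name, generating mean
#' and sd in native units, and whether it is a climate factor. The
#' aspect class is special-cased by the generator (integers 1-4).
#'
#' @param name one of the [impact_factors()] names.
#' @param mean,sd generating mean and sd (sd >= 0).
#' @param is_climate logical; TRUE for temperature and precipitation.
#' @return a list of class \code{"factor_spec"}.
#' @export
factor_spec <- function(name, mean, sd, is_climate = FALSE) {
  stopifnot(name %in% impact_factors(), is.finite(mean), sd >= 0)
  structure(list(name = name, mean = mean, sd = sd,
                 is_climate = isTRUE(is_climate)), class = "factor_spec")
}

#' Default factor specifications
#'
#' Native-unit generating distributions chosen to resemble montane
#' deciduous-forest settings: aspect class uniform on 1-4, terrain
#' relief around 300 m, mountaintop effect around 5 km^2, January mean
#' temperature around -5 degrees C, annual precipitation around 1000 mm.
#' Exactly two factors are flagged climatic.
#'
#' @return named list of [factor_spec()]s in [impact_factors()] order.
#' @export
default_factor_specs <- function() {
  list(
    aspect_class    = factor_spec("aspect_class", 2.5, sqrt(1.25)),
    relief_m        = factor_spec("relief_m", 300, 80),
    mountaintop_m2  = factor_spec("mountaintop_m2", 5e6, 1.5e6),
    jan_temp_c      = factor_spec("jan_temp_c", -5, 3, is_climate = TRUE),
    annual_precip_mm = factor_spec("annual_precip_mm", 1000, 250,
                                   is_climate = TRUE))
}

#' Ground-truth parameters of one synthetic mountain
#'
#' Holds everything the generator needs for one mountain and everything
#' a recovery test needs to check: the per-factor weight-cloud digests
#' (truth for Ex/En/He of the site weights), the scale mapping
#' normalized weights to raw regression coefficients, the intercept and
#' noise sd of the height model, and the mountain's region and moisture
#' labels.
#'
#' @param mountain_id identifier.
#' @param weight_digests named list of [cloud()] digests, one per factor;
#'   truth Ex values must be >= 0 and sum to 1 (+-1e-9).
#' @param coefficient_scale m of elevation per unit weight (> 0).
#' @param intercept height-model intercept b (m).
#' @param noise_sd residual sd sigma (m, >= 0).
#' @param region study-region label.
#' @param moisture \code{"humid"} or \code{"arid_semiarid"}.
#' @return list of class \code{"unit_truth"}.
#' @export
unit_truth <- function(mountain_id, weight_digests,
                       coefficient_scale = 300, intercept = 1800,
                       noise_sd = 30, region = "east_asia",
                       moisture = c("humid", "arid_semiarid")) {
  moisture <- match.arg(moisture)
  stopifnot(is.list(weight_digests),
            all(vapply(weight_digests, inherits, logical(1), "cloud")))
  ex <- vapply(weight_digests, `[[`, numeric(1), "Ex")
  if (any(ex < 0)) stop("truth weight Ex values must be >= 0")
  if (abs(sum(ex) - 1) > 1e-9)
    stop("truth weight Ex values must sum to 1 (got ", sum(ex), ")")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (coefficient_scale <= 0) stop("'coefficient_scale' must be > 0")
  structure(list(mountain_id = as.character(mountain_id),
                 weight_digests = weight_digests,
                 coefficient_scale = coefficient_scale,
                 intercept = intercept, noise_sd = noise_sd,
                 region = region, moisture = moisture),
            class = "unit_truth")
}

# deterministic substream seed from a master seed and a counter;
# stays inside 32-bit integer range
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + 10007 * as.numeric(counter)) %%
               2147483647)
}

# forward-cloud draw of one normalized nonnegative weight vector
draw_weight_vector <- function(digests) {
  w <- vapply(digests, function(d) {
    En_prime <- stats::rnorm(1, d$En, d$He)
    stats::rnorm(1, d$Ex, abs(En_prime))
  }, numeric(1))
  w[w < 0] <- 0
  if (sum(w) == 0)   # pathological draw: fall back to the truth centre
    w <- vapply(digests, `[[`, numeric(1), "Ex")
  w / sum(w)
}

#' Generate a synthetic elevation grid
#'
#' A smooth substrate for terrain-factor tests: the sum of Gaussian
#' hills plus optional low-amplitude spatially correlated noise
#' (moving-average-smoothed white noise). Deterministic per seed.
#'
#' @param extent_deg square extent in decimal degrees.
#' @param cell_size_m ground cell size in metres (> 0); the cell count
#'   derives from the extent at ~111.32 km per degree.
#' @param n_peaks number of Gaussian hills (>= 1).
#' @param seed integer seed.
#' @param peaks optional data.frame(lon, lat, height_m, width_m) fixing
#'   the hills; defaults to seeded random placement inside the extent.
#' @param base_elevation_m constant base level (default 500 m).
#' @param noise_amp_m amplitude of the correlated noise (default 5 m;
#'   0 for an analytic surface).
#' @param xll,yll lower-left corner (degrees).
#' @return an [elev_grid()].
#' @export
generate_elevation_grid <- function(extent_deg = 0.02, cell_size_m = 30,
                                    n_peaks = 3, seed = 1, peaks = NULL,
                                    base_elevation_m = 500,
                                    noise_amp_m = 5, xll = 100, yll = 40) {
  if (cell_size_m <= 0) stop("'cell_size_m' must be > 0")
  if (extent_deg <= 0) stop("'extent_deg' must be > 0")
  if (n_peaks < 1L) stop("'n_peaks' must be >= 1")
  m_per_deg <- 111320
  n_cells <- max(5L, as.integer(round(extent_deg * m_per_deg / cell_size_m)))
  cellsize_deg <- extent_deg / n_cells
  set.seed(as.integer(seed))
  if (is.null(peaks)) {
    peaks <- data.frame(
      lon = xll + stats::runif(n_peaks, 0.2, 0.8) * extent_deg,
      lat = yll + stats::runif(n_peaks, 0.2, 0.8) * extent_deg,
      height_m = stats::runif(n_peaks, 800, 2000),
      width_m = stats::runif(n_peaks, 0.1, 0.25) * extent_deg * m_per_deg)
  }
  # cell-centre coordinates; row 1 = north
  xc <- xll + (seq_len(n_cells) - 0.5) * cellsize_deg
  yc <- yll + (rev(seq_len(n_cells)) - 0.5) * cellsize_deg
  z <- matrix(base_elevation_m, n_cells, n_cells)
  for (p in seq_len(nrow(peaks))) {
    dx <- outer(rep(1, n_cells), (xc - peaks$lon[p]) * m_per_deg)
    dy <- outer((yc - peaks$lat[p]) * m_per_deg, rep(1, n_cells))
    z <- z + peaks$height_m[p] * exp(-(dx^2 + dy^2) / (2 * peaks$width_m[p]^2))
  }
  if (noise_amp_m > 0) {
    noise <- matrix(stats::rnorm(n_cells^2), n_cells, n_cells)
    k <- 3L  # smoothing half-width: short-range correlated noise
    sm <- matrix(0, n_cells, n_cells)
    for (i in seq_len(n_cells)) for (j in seq_len(n_cells)) {
      ri <- max(1L, i - k):min(n_cells, i + k)
      cj <- max(1L, j - k):min(n_cells, j + k)
      sm[i, j] <- mean(noise[ri, cj])
    }
    z <- z + noise_amp_m * sm / stats::sd(as.vector(sm))
  }
  grid <- elev_grid(z, xll = xll, yll = yll, cellsize = cellsize_deg,
                    cell_m = extent_deg * m_per_deg / n_cells)
  attr(grid, "peaks") <- peaks
  grid
}

#' Generate one synthetic analysis mountain
#'
#' Per site, a normalized weight vector is drawn by forward-cloud
#' sampling from the truth digests (clipped at zero and renormalized).
#' Factor values are drawn independently per point; the raw regression
#' coefficients are then set to
#' \code{a_i = coefficient_scale * w_i / sd(x_i)} (sample sd), which
#' makes the standardized coefficients exactly proportional to the drawn
#' weights — so in the noiseless limit the per-site regression recovers
#' the drawn weight vector exactly. Elevation is
#' \code{y = sum(a_i x_i) + b + eps}, \code{eps ~ N(0, sigma^2)}.
#'
#' @param truth a [unit_truth()].
#' @param n_sites number of sites (>= 1).
#' @param points_per_site points per site; must be at least
#'   \code{n_factors + 2} for an identifiable regression.
#' @param seed integer seed.
#' @param factor_specs list from [default_factor_specs()].
#' @param site_offset integer offset for site numbering.
#' @param center_lon,center_lat mountain centre for coordinates.
#' @return list: \code{points} (data.frame), \code{site_weights}
#'   (matrix rows = factors, cols = sites: the drawn truth vectors),
#'   \code{truth}.
#' @export
generate_unit <- function(truth, n_sites, points_per_site, seed = 1,
                          factor_specs = default_factor_specs(),
                          site_offset = 0L,
                          center_lon = 110, center_lat = 35) {
  stopifnot(inherits(truth, "unit_truth"), n_sites >= 1L)
  fnames <- names(factor_specs)
  if (points_per_site < length(fnames) + 2L)
    stop("'points_per_site' must be >= number of factors + 2 (",
         length(fnames) + 2L, ") for an identifiable regression")
  digests <- truth$weight_digests[fnames]
  if (anyNA(names(digests)))
    stop("truth digests must cover every factor in 'factor_specs'")
  set.seed(as.integer(seed))
  pts <- list()
  SW <- matrix(NA_real_, length(fnames), n_sites,
               dimnames = list(fnames, rep("", n_sites)))
  for (s in seq_len(n_sites)) {
    w <- draw_weight_vector(digests)
    SW[, s] <- w
    X <- sapply(fnames, function(f) {
      sp <- factor_specs[[f]]
      if (f == "aspect_class") sample(1:4, points_per_site, replace = TRUE)
      else stats::rnorm(points_per_site, sp$mean, sp$sd)
    })
    sx <- apply(X, 2, stats::sd)
    if (any(sx == 0)) stop("degenerate factor draw (zero sample sd)")
    a <- truth$coefficient_scale * w / sx
    y <- as.vector(X %*% a) + truth$intercept +
      stats::rnorm(points_per_site, 0, truth$noise_sd)
    site_id <- sprintf("%s_S%02d", truth$mountain_id, s + site_offset)
    slon <- center_lon + stats::runif(1, -0.15, 0.15)
    slat <- center_lat + stats::runif(1, -0.15, 0.15)
    d <- data.frame(
      mountain_id = truth$mountain_id, site_id = site_id,
      point_id = sprintf("%s_P%03d", site_id, seq_len(points_per_site)),
      lon = slon + stats::runif(points_per_site, -0.02, 0.02),
      lat = slat + stats::runif(points_per_site, -0.02, 0.02),
      elevation_m = y, stringsAsFactors = FALSE)
    d[fnames] <- as.data.frame(X)
    pts[[s]] <- d
    colnames(SW)[s] <- site_id
  }
  list(points = do.call(rbind, pts), site_weights = SW, truth = truth)
}

#' Generate a synthetic annual NDVI series
#'
#' \code{value_i = intercept + slope * i + N(0, noise_sd^2)} for
#' i = 1..n_years; deterministic per seed.
#'
#' @param slope trend in NDVI per year.
#' @param intercept baseline NDVI.
#' @param noise_sd interannual noise sd.
#' @param n_years series length (>= 2).
#' @param seed integer seed.
#' @return numeric vector of length \code{n_years}.
#' @export
generate_ndvi_series <- function(slope, intercept = 0.5, noise_sd = 0.02,
                                 n_years = 15, seed = 1) {
  if (n_years < 2L) stop("'n_years' must be >= 2")
  set.seed(as.integer(seed))
  i <- seq_len(n_years)
  intercept + slope * i + stats::rnorm(n_years, 0, noise_sd)
}

#' Default synthetic-study configuration
#'
#' Mirrors the study hierarchy the analysis assumes: 28 mountains,
#' 107 sites (four sites for the first 23 mountains, three for the
#' last five), 4021 location points spread evenly over sites, 15 years
#' of NDVI. The last five mountains are arid/semi-arid with
#' precipitation-dominant truth weights; the rest are humid with
#' temperature-dominant truth (expectations centred on
#' hemisphere-average factor contributions: aspect 4%, relief 5%,
#' mountaintop 20%, temperature 47%, precipitation 24%). A
#' deterministic per-mountain wobble (+-0.10) trades weight between the
#' dominant climate factor and the mountaintop effect so mountains are
#' heterogeneous — truth comprehensive sensitivity spreads by roughly a
#' third either way, as real ranges do — without ever flipping the
#' truth dominance class. Regions split 11 East Asia / 11 Europe /
#' 6 other.
#'
#' @param n_mountains,n_sites,n_points hierarchy totals.
#' @param n_arid number of arid/semi-arid mountains (taken from the end).
#' @param n_years NDVI series length.
#' @param noise_sd height-model residual sd (m).
#' @param En,He truth entropy and hyperentropy of every factor weight.
#' @param ndvi_gain NDVI response per unit of truth CSI (the monotone
#'   link the validation stage should detect).
#' @param ndvi_noise_sd interannual NDVI noise sd.
#' @return list of class \code{"study_config"}.
#' @export
default_study_config <- function(n_mountains = 28, n_sites = 107,
                                 n_points = 4021, n_arid = 5,
                                 n_years = 15, noise_sd = 30,
                                 En = 0.05, He = 0.01,
                                 ndvi_gain = 0.002,
                                 ndvi_noise_sd = 0.02) {
  stopifnot(n_mountains >= 1, n_sites >= n_mountains,
            n_arid >= 0, n_arid < n_mountains)
  base_s <- n_sites %/% n_mountains
  rem_s <- n_sites %% n_mountains
  sites_per_mountain <- rep(base_s, n_mountains) +
    c(rep(1L, rem_s), rep(0L, n_mountains - rem_s))
  humid_ex <- c(aspect_class = 0.04, relief_m = 0.05,
                mountaintop_m2 = 0.20, jan_temp_c = 0.47,
                annual_precip_mm = 0.24)
  arid_ex <- c(aspect_class = 0.05, relief_m = 0.05,
               mountaintop_m2 = 0.20, jan_temp_c = 0.25,
               annual_precip_mm = 0.45)
  n_ea <- ceiling(n_mountains * 11 / 28)
  n_eu <- ceiling(n_mountains * 11 / 28)
  regions <- c(rep("east_asia", n_ea), rep("europe", n_eu),
               rep("other", max(0, n_mountains - n_ea - n_eu)))[1:n_mountains]
  mountains <- lapply(seq_len(n_mountains), function(m) {
    arid <- m > n_mountains - n_arid
    ex <- if (arid) arid_ex else humid_ex
    # deterministic per-mountain heterogeneity: the dominant climate
    # factor trades weight with the mountaintop effect, emulating the
    # wide spread of comprehensive sensitivity seen across real ranges
    delta <- 0.10 * sin(2.399963 * m)   # golden-angle wobble in [-0.1, 0.1]
    dom <- if (arid) "annual_precip_mm" else "jan_temp_c"
    ex[[dom]] <- ex[[dom]] + delta
    ex[["mountaintop_m2"]] <- ex[["mountaintop_m2"]] - delta
    digests <- lapply(ex, function(e) cloud(e, En, He))
    list(
      truth = unit_truth(
        mountain_id = sprintf("M%02d", m),
        weight_digests = digests,
        coefficient_scale = 300,
        intercept = 2600 - 40 * m,   # higher limits at lower latitude index
        noise_sd = noise_sd,
        region = regions[m],
        moisture = if (arid) "arid_semiarid" else "humid"),
      n_sites = sites_per_mountain[m],
      center_lon = switch(regions[m], east_asia = 100 + 3 * (m %% 12),
                          europe = 0 + 3 * (m %% 12), 60 + 5 * (m %% 7)),
      center_lat = 47 - 20 * (m - 1) / max(1, n_mountains - 1))
  })
  structure(list(mountains = mountains, n_points = n_points,
                 n_sites = n_sites, n_years = n_years,
                 ndvi_gain = ndvi_gain, ndvi_noise_sd = ndvi_noise_sd),
            class = "study_config")
}

# truth-implied sensitivity table for a config (used by recovery tests)
truth_sensitivity <- function(config, point_counts) {
  N <- sum(point_counts)
  rows <- lapply(config$mountains, function(m) {
    tr <- m$truth
    si <- function(f) {
      d <- tr$weight_digests[[f]]
      d$Ex / (d$En + d$He) * point_counts[[tr$mountain_id]] / N * 100
    }
    tsi <- si("jan_temp_c"); psi <- si("annual_precip_mm")
    data.frame(mountain_id = tr$mountain_id, tsi = tsi, psi = psi,
               csi = tsi + psi, p_temp = tsi / (tsi + psi),
               region = tr$region, moisture = tr$moisture,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a complete synthetic study
#'
#' Runs [generate_unit()] for every configured mountain (each on its own
#' derived seed stream, so any mountain can be regenerated
#' independently), allocates the configured total of location points
#' evenly over sites (earlier sites absorb the remainder), and attaches
#' per-point NDVI series whose expected change rate increases with the
#' mountain's truth comprehensive sensitivity — the monotone link the
#' validation stage is meant to detect. Reproducible per seed.
#'
#' @param config a [default_study_config()] (or compatible list).
#' @param seed master integer seed.
#' @return list of class \code{"synthetic_study"}: \code{points},
#'   \code{ndvi} (long data.frame point_id/year/ndvi),
#'   \code{site_weights} (drawn truth weight matrix),
#'   \code{truth} (per-mountain truth table incl. truth indices),
#'   \code{config}, \code{seed}.
#' @export
generate_study <- function(config = default_study_config(), seed = 1) {
  ids <- vapply(config$mountains, function(m) m$truth$mountain_id, "")
  if (anyDuplicated(ids)) stop("duplicate mountain ids in config")
  n_mountains <- length(ids)
  sites_per <- vapply(config$mountains, function(m) as.integer(m$n_sites),
                      integer(1))
  n_sites <- sum(sites_per)
  base_p <- config$n_points %/% n_sites
  rem_p <- config$n_points %% n_sites
  pts_per_site_global <- rep(base_p, n_sites) +
    c(rep(1L, rem_p), rep(0L, n_sites - rem_p))
  if (base_p < length(impact_factors()) + 2L)
    stop("too few points per site for identifiable regressions")
  site_cursor <- 0L
  all_pts <- list()
  SW <- NULL
  for (m in seq_len(n_mountains)) {
    cfg <- config$mountains[[m]]
    npts <- pts_per_site_global[site_cursor + seq_len(cfg$n_sites)]
    # generate_unit draws a fixed count per site; call per block of equal
    # counts so the configured totals are hit exactly
    parts <- list(); sw_parts <- list()
    off <- 0L
    for (cnt in unique(npts)) {
      k <- sum(npts == cnt)
      u <- generate_unit(cfg$truth, n_sites = k, points_per_site = cnt,
                         seed = derive_seed(seed, m * 1000L + off),
                         site_offset = off,
                         center_lon = cfg$center_lon,
                         center_lat = cfg$center_lat)
      parts[[length(parts) + 1L]] <- u$points
      sw_parts[[length(sw_parts) + 1L]] <- u$site_weights
      off <- off + k
    }
    all_pts[[m]] <- do.call(rbind, parts)
    SW <- cbind(SW, do.call(cbind, sw_parts))
    site_cursor <- site_cursor + cfg$n_sites
  }
  points <- do.call(rbind, all_pts)
  rownames(points) <- NULL
  pc_tab <- table(points$mountain_id)
  point_counts <- stats::setNames(as.integer(pc_tab), names(pc_tab))
  truth_tbl <- truth_sensitivity(config, point_counts)
  # NDVI: per-point series with mountain-level expected |slope|
  # proportional to the truth CSI
  ndvi_rows <- vector("list", n_mountains)
  for (m in seq_len(n_mountains)) {
    mid <- ids[m]
    mu <- config$ndvi_gain * truth_tbl$csi[truth_tbl$mountain_id == mid]
    p_ids <- points$point_id[points$mountain_id == mid]
    set.seed(derive_seed(seed, 500000L + m))
    slopes <- stats::rnorm(length(p_ids), mu, mu * 0.1)
    series <- lapply(seq_along(p_ids), function(k)
      generate_ndvi_series(slopes[k], intercept = 0.5,
                           noise_sd = config$ndvi_noise_sd,
                           n_years = config$n_years,
                           seed = derive_seed(seed, 900000L + m * 1000L + k)))
    ndvi_rows[[m]] <- data.frame(
      point_id = rep(p_ids, each = config$n_years),
      year = rep(seq_len(config$n_years), length(p_ids)),
      ndvi = unlist(series), stringsAsFactors = FALSE)
  }
  ndvi <- do.call(rbind, ndvi_rows)
  rownames(ndvi) <- NULL
  structure(list(points = points, ndvi = ndvi, site_weights = SW,
                 truth = truth_tbl, config = config,
                 seed = as.integer(seed)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic_study: %d mountains, %d sites, %d points, %d NDVI years (seed %d)\n",
    length(unique(x$points$mountain_id)),
    length(unique(x$points$site_id)), nrow(x$points),
    x$config$n_years, x$seed))
  invisible(x)
}
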