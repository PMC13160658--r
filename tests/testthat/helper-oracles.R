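# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (loops, closed forms) so they share no code with the
# implementation paths they check.

# moving-window max-min by exhaustive scan
oracle_relief <- function(z, window) {
  half <- window %/% 2
  out <- matrix(NA_real_, nrow(z), ncol(z))
  for (i in seq_len(nrow(z))) for (j in seq_len(ncol(z))) {
    vals <- c()
    for (a in (i - half):(i + half)) for (b in (j - half):(j + half)) {
      if (a >= 1 && a <= nrow(z) && b >= 1 && b <= ncol(z) &&
          !is.na(z[a, b])) vals <- c(vals, z[a, b])
    }
    if (length(vals)) out[i, j] <- max(vals) - min(vals)
  }
  out
}

# OLS coefficients by explicit normal equations
oracle_ols <- function(X, y) {
  Xd <- cbind(1, as.matrix(X))
  solve(t(Xd) %*% Xd, t(Xd) %*% y)[, 1]
}

# closed-form simple-regression slope and Pearson r
oracle_slope_r <- function(x, y) {
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  list(slope = sxy / sum((x - mean(x))^2),
       r = sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
}

# Spearman rho as Pearson on average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  oracle_slope_r(rx, ry)$r
}

# greedy spacing/elevation filter re-implemented independently
oracle_filter <- function(points, min_spacing, min_elevation) {
  kept_idx <- integer(0)
  for (i in seq_len(nrow(points))) {
    if (points$elevation_m[i] < min_elevation) next
    ok <- TRUE
    for (k in kept_idx) {
      d <- geosphere::distHaversine(
        c(points$lon[i], points$lat[i]),
        c(points$lon[k], points$lat[k]))
      if (d < min_spacing) { ok <- FALSE; break }
    }
    if (ok) kept_idx <- c(kept_idx, i)
  }
  kept_idx
}

# small truth object shared by recovery tests
make_truth <- function(ex = c(aspect_class = 0.1, relief_m = 0.15,
                              mountaintop_m2 = 0.15, jan_temp_c = 0.4,
                              annual_precip_mm = 0.2),
                       En = 0.05, He = 0.01, noise_sd = 5, id = "T1",
                       ...) {
  unit_truth(id, lapply(ex, function(e) cloud(e, En, He)),
             noise_sd = noise_sd, ...)
}
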