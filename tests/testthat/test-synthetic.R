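test_that("synthetic elevation grids honour their peak configuration", {
  pk <- data.frame(lon = 100.0015, lat = 40.0015, height_m = 1000,
                   width_m = 40)
  g <- generate_elevation_grid(extent_deg = 0.003, cell_size_m = 30,
                               n_peaks = 1, seed = 1, peaks = pk,
                               noise_amp_m = 0, xll = 100, yll = 40)
  # noiseless single hill: global maximum at the cell containing the peak
  idx <- which(g$values == max(g$values), arr.ind = TRUE)
  ctr <- cloudsens:::cell_index(g, 100.0015, 40.0015)
  expect_equal(unname(idx[1, ]), unname(ctr[1, ]))
  expect_true(all(is.finite(g$values)))

  # determinism: same seed, identical grids
  g1 <- generate_elevation_grid(seed = 9, extent_deg = 0.004)
  g2 <- generate_elevation_grid(seed = 9, extent_deg = 0.004)
  expect_identical(g1, g2)

  # three configured peaks are all local maxima (brute-force scan)
  pk <- data.frame(lon = c(100.001, 100.003, 100.0045),
                   lat = c(40.0045, 40.0025, 40.001),
                   height_m = c(900, 1100, 1000), width_m = c(35, 35, 35))
  g <- generate_elevation_grid(extent_deg = 0.006, cell_size_m = 30,
                               n_peaks = 3, seed = 2, peaks = pk,
                               noise_amp_m = 0, xll = 100, yll = 40)
  z <- g$values
  for (p in seq_len(3)) {
    ij <- cloudsens:::cell_index(g, pk$lon[p], pk$lat[p])
    i <- ij[1, "row"]; j <- ij[1, "col"]
    nb <- z[max(1, i - 1):min(nrow(z), i + 1),
            max(1, j - 1):min(ncol(z), j + 1)]
    expect_equal(max(nb), z[i, j])
  }
  expect_error(generate_elevation_grid(cell_size_m = 0), "> 0")
})

test_that("per-site weight draws are valid and seeds give reproducibility", {
  tr <- make_truth()
  u <- generate_unit(tr, n_sites = 50, points_per_site = 10, seed = 12)
  expect_true(all(u$site_weights >= 0))
  expect_equal(colSums(u$site_weights), rep(1, 50), tolerance = 1e-9,
               ignore_attr = TRUE)
  u2 <- generate_unit(tr, n_sites = 50, points_per_site = 10, seed = 12)
  expect_identical(u, u2)
  expect_error(generate_unit(tr, 2, points_per_site = 6), "\\+ 2")
})

test_that("NDVI series generation matches its linear model", {
  s <- generate_ndvi_series(0.01, intercept = 0.3, noise_sd = 0,
                            n_years = 15)
  expect_equal(ndvi_slope(s), 0.01, tolerance = 1e-12)
  s <- generate_ndvi_series(0, intercept = 0.3, noise_sd = 0, n_years = 5)
  expect_equal(s, rep(0.3, 5))
  expect_equal(ndvi_slope(s), 0)
  expect_error(generate_ndvi_series(0.01, n_years = 1), ">= 2")

  # Monte-Carlo slope recovery over replicate noisy series
  slopes <- sapply(1:1000, function(k)
    ndvi_slope(generate_ndvi_series(0.01, noise_sd = 0.005, n_years = 15,
                                    seed = k)))
  expect_lt(abs(mean(slopes) - 0.01), 0.001)
})

test_that("study generation books points, classes and reproducibility", {
  cfg <- default_study_config()
  s <- generate_study(cfg, seed = 3)
  expect_equal(length(unique(s$points$mountain_id)), 28L)
  expect_equal(length(unique(s$points$site_id)), 107L)
  expect_equal(nrow(s$points), 4021L)
  expect_equal(nrow(s$ndvi), 4021L * 15L)
  # moisture partition matches the configuration
  expect_equal(sum(s$truth$moisture == "arid_semiarid"), 5L)
  expect_equal(sum(s$truth$moisture == "humid"), 23L)
  expect_equal(as.vector(table(s$truth$region)[c("east_asia", "europe",
                                                 "other")]),
               c(11L, 11L, 6L))
  # every point belongs to exactly one site and one mountain
  site2mt <- unique(s$points[, c("site_id", "mountain_id")])
  expect_equal(nrow(site2mt), 107L)
  expect_false(anyDuplicated(s$points$point_id) > 0)

  # byte-for-byte determinism of the serialized study
  s2 <- generate_study(cfg, seed = 3)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_points(s$points, f1); write_points(s2$points, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s$ndvi, s2$ndvi)

  cfg_bad <- cfg
  cfg_bad$mountains[[2]]$truth$mountain_id <- "M01"
  expect_error(generate_study(cfg_bad, seed = 1), "duplicate")
})

test_that("truth constructor rejects invalid weight digests", {
  expect_error(make_truth(ex = c(aspect_class = 0.5, relief_m = 0.2,
                                 mountaintop_m2 = 0.2, jan_temp_c = 0.2,
                                 annual_precip_mm = 0.2)), "sum to 1")
  expect_error(make_truth(noise_sd = -1), ">= 0")
})

test_that("full pipeline recovers truth digests and dominance", {
  # noiseless limit: per-factor digest Ex equals truth Ex to 1e-6
  tr <- make_truth(En = 0, He = 0, noise_sd = 0)
  u <- generate_unit(tr, n_sites = 5, points_per_site = 10, seed = 21)
  wm <- suppressWarnings(build_weight_matrix(u$points))
  dg <- weight_clouds(wm$weights, wm$mountain_ids)
  truth_ex <- c(0.1, 0.15, 0.15, 0.4, 0.2)
  expect_equal(dg$Ex[match(impact_factors(), dg$factor)], truth_ex,
               tolerance = 1e-6)

  # estimator consistency: doubling points per site leaves the
  # truth-recovery bias unchanged within Monte-Carlo error
  tr <- make_truth()
  bias <- sapply(c(10, 20), function(pps) {
    ex_hat <- rowMeans(sapply(1:6, function(sd) {
      u <- generate_unit(tr, n_sites = 40, points_per_site = pps,
                         seed = 100 + sd)
      wm <- build_weight_matrix(u$points)
      dg <- weight_clouds(wm$weights, wm$mountain_ids)
      dg$Ex[match(impact_factors(), dg$factor)]
    }))
    ex_hat - c(0.1, 0.15, 0.15, 0.4, 0.2)
  })
  expect_lt(max(abs(bias[, 1] - bias[, 2])), 0.02)

  # humid dominance fraction tracks the truth-implied fraction
  frac <- sapply(1:20, function(sd) {
    cfg <- default_study_config(n_mountains = 6, n_sites = 150,
                                n_points = 1800, n_arid = 2)
    s <- generate_study(cfg, seed = sd)
    fit <- ulmdb_sensitivity(
      s$points, mountain_meta = s$truth[, c("mountain_id", "region",
                                            "moisture")])
    rec <- fit$records
    mean(rec$p_temp[rec$moisture == "humid"] > 0.5)
  })
  truth_frac <- 1  # humid truth weights are temperature-dominant
  expect_lt(abs(mean(frac) - truth_frac), 0.10)
})
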