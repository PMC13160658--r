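# analytic plane dipping toward a given azimuth (degrees cw from north)
plane_grid <- function(azimuth_deg, n = 7, slope = 0.1, cell_m = 30) {
  a <- azimuth_deg * pi / 180
  z <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x_e <- j * cell_m
    y_n <- (n - i) * cell_m      # row 1 = north
    # elevation decreases toward the dip azimuth
    z[i, j] <- 1000 - slope * (sin(a) * x_e + cos(a) * y_n)
  }
  elev_grid(z, cell_m = cell_m)
}

test_that("aspect of analytic planes matches the dip azimuth", {
  az <- compute_aspect(plane_grid(180))
  expect_true(all(abs(az[2:6, 2:6] - 180) < 1e-9))

  # flat grid: undefined everywhere
  expect_true(all(is.na(compute_aspect(elev_grid(matrix(5, 5, 5))))))

  for (a in c(135, 45.5, 301.25)) {
    az <- compute_aspect(plane_grid(a))
    expect_true(all(abs(az[2:6, 2:6] - a) < 1e-6), label = paste("az", a))
  }
  expect_error(compute_aspect(elev_grid(matrix(1:4, 2, 2))), "3 x 3")
})

test_that("aspect classification follows the four-class convention", {
  expect_identical(classify_aspect(0), 1L)     # due north: shady
  expect_identical(classify_aspect(180), 3L)   # due south: sunny
  expect_identical(classify_aspect(NA), NA_integer_)
  # rotating the dip through the cardinal azimuths cycles the classes
  expect_identical(classify_aspect(c(0, 90, 180, 270)),
                   c(1L, 4L, 3L, 2L))
  expect_identical(classify_aspect(c(44.999, 45, 134.999, 135, 224.999,
                                     225, 314.999, 315)),
                   c(1L, 2L, 4L, 3L, 3L, 4L, 2L, 1L))
  expect_warning(out <- classify_aspect(-90), "normalized")
  expect_identical(out, 2L)
})

test_that("terrain relief equals the brute-force window scan", {
  expect_true(all(terrain_relief(elev_grid(matrix(7, 6, 6)), 3) == 0))

  # window holding the 1500/700 pair
  z <- matrix(1000, 3, 3); z[1, 1] <- 1500; z[3, 3] <- 700
  expect_equal(terrain_relief(elev_grid(z), 3)[2, 2], 800)

  set.seed(14)
  z <- matrix(runif(81, 500, 2500), 9, 9)
  z[4, 6] <- NA  # a nodata hole
  g <- elev_grid(z, nodata = -9999)
  g$values[is.na(z)] <- -9999
  for (w in c(3, 5)) {
    expect_equal(terrain_relief(g, w), oracle_relief(z, w),
                 ignore_attr = TRUE)
  }
  expect_error(terrain_relief(g, 4), "odd")

  # translation invariance
  g2 <- g; g2$values[g2$values != -9999] <- g2$values[g2$values != -9999] + 123
  expect_equal(terrain_relief(g2, 3), terrain_relief(g, 3))
})

test_that("mountaintop effect counts qualifying cells times cell area", {
  z <- matrix(seq(700, 1500, length.out = 16), 4, 4)
  g <- elev_grid(z, cell_m = 30)
  mask <- matrix(TRUE, 4, 4)
  expect_equal(mountaintop_effect(g, mask, 2000), 0)

  # exactly 4 qualifying cells at 30 m cells
  thr <- sort(z, decreasing = TRUE)[5]
  expect_equal(mountaintop_effect(g, mask, thr), 4 * 900)

  set.seed(21)
  z <- matrix(runif(100, 0, 100), 10, 10)
  mask <- matrix(runif(100) > 0.3, 10, 10)
  g <- elev_grid(z, cell_m = 30)
  for (thr in c(10, 50, 90)) {
    expect_equal(mountaintop_effect(g, mask, thr),
                 sum(mask & z > thr) * 900)
  }
  # monotone non-increasing in the threshold
  areas <- sapply(seq(0, 100, by = 5), function(t)
    mountaintop_effect(g, mask, t))
  expect_true(all(diff(areas) <= 0))
  expect_error(mountaintop_effect(g, mask & FALSE, 10), "no cells")
})

test_that("climate means implement the january and annual-total modes", {
  arr <- array(3, dim = c(4, 4, 24))
  st <- monthly_stack(arr)
  expect_true(all(climate_mean(st, "january")$values == 3))
  expect_true(all(climate_mean(st, "annual_total_mean")$values == 36))

  # two januaries 0 and 2
  arr <- array(0, dim = c(2, 2, 24)); arr[, , 13] <- 2
  expect_true(all(climate_mean(monthly_stack(arr), "january")$values == 1))

  set.seed(5)
  arr <- array(rnorm(3 * 3 * 24), dim = c(3, 3, 24))
  st <- monthly_stack(arr)
  jan_ref <- (arr[, , 1] + arr[, , 13]) / 2
  ann_ref <- (apply(arr[, , 1:12], c(1, 2), sum) +
                apply(arr[, , 13:24], c(1, 2), sum)) / 2
  expect_equal(climate_mean(st, "january")$values, jan_ref)
  expect_equal(climate_mean(st, "annual_total_mean")$values, ann_ref)

  expect_error(monthly_stack(array(0, dim = c(2, 2, 13))), "multiple of 12")
})

test_that("point sampling is nearest-cell with flagged misses", {
  z <- matrix(1:25, 5, 5)
  g <- elev_grid(z, xll = 100, yll = 40, cellsize = 0.1)
  # centre of cell (row 5 = south row, col 1): value z[5, 1] = 5
  s <- sample_at_points(g, data.frame(lon = 100.05, lat = 40.05))
  expect_equal(s$value, z[5, 1])

  g$values[3, 3] <- g$nodata
  s <- sample_at_points(g, data.frame(lon = 100.25, lat = 40.25))
  expect_true(is.na(s$value) && s$nodata && !s$outside)

  expect_warning(
    s <- sample_at_points(g, data.frame(lon = 99, lat = 40.1)),
    "outside")
  expect_true(s$outside)

  set.seed(31)
  pts <- data.frame(lon = runif(100, 100, 100.5), lat = runif(100, 40, 40.5))
  s <- sample_at_points(elev_grid(z, xll = 100, yll = 40, cellsize = 0.1),
                        pts)
  # index-arithmetic oracle
  col <- floor((pts$lon - 100) / 0.1) + 1
  row <- 5 - (floor((pts$lat - 40) / 0.1) + 1) + 1
  expect_equal(s$value, z[cbind(row, col)])
})

test_that("point filtering enforces spacing and elevation greedily", {
  # two points ~200 m apart: second rejected
  p <- data.frame(lon = c(100, 100.0018), lat = c(40, 40),
                  elevation_m = c(1000, 1000))
  out <- filter_points(p, min_spacing = 400)
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "report")$reason[2], "too_close")

  # below the 700 m floor
  p <- data.frame(lon = 100, lat = 40, elevation_m = 650)
  out <- filter_points(p)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "report")$reason, "below_min_elevation")

  set.seed(19)
  p <- data.frame(lon = runif(50, 100, 100.02), lat = runif(50, 40, 40.02),
                  elevation_m = runif(50, 600, 900))
  out <- filter_points(p, min_spacing = 400, min_elevation = 700)
  expect_equal(which(attr(out, "report")$kept), oracle_filter(p, 400, 700))
  # kept set satisfies both rules pairwise
  expect_true(all(out$elevation_m >= 700))
  if (nrow(out) > 1) {
    dmat <- geosphere::distm(cbind(out$lon, out$lat))
    expect_true(all(dmat[upper.tri(dmat)] >= 400))
  }
})

test_that("ASCII grid writer and reader round-trip", {
  g <- generate_elevation_grid(extent_deg = 0.003, cell_size_m = 30,
                               n_peaks = 1, seed = 2)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, path)
  g2 <- read_ascii_grid(path)
  expect_equal(g2$values, g$values, tolerance = 1e-8)
  expect_equal(g2$xll, g$xll)
  expect_equal(g2$cellsize, g$cellsize)
})
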