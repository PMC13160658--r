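test_that("single-factor index implements Ex/(En+He) x Ni/N x scale", {
  expect_equal(single_factor_si(cloud(0.5, 0.04, 0.01), Ni = 10, N = 100),
               100)
  expect_equal(single_factor_si(cloud(0.5, 0.04, 0.01), Ni = 0, N = 100),
               0)
  # independent recomputation on random digests/counts
  set.seed(55)
  for (k in 1:20) {
    Ex <- runif(1); En <- runif(1, 0.01, 0.3); He <- runif(1, 0, 0.1)
    Ni <- sample(0:500, 1); N <- Ni + sample(1:4000, 1)
    sc <- sample(c(1, 100), 1)
    expect_equal(single_factor_si(cloud(Ex, En, He), Ni, N, scale = sc),
                 Ex / (En + He) * Ni / N * sc, tolerance = 1e-12)
  }
  # degenerate crisp cloud: epsilon floor by default, Inf on request
  expect_warning(v <- single_factor_si(cloud(0.5, 0, 0), 1, 10), "floored")
  expect_equal(v, 0.5 / 1e-6 * 0.1 * 100)
  expect_identical(single_factor_si(cloud(0.5, 0, 0), 1, 10,
                                    zero_policy = "infinite"), Inf)
})

test_that("comprehensive index and contribution rates are consistent", {
  expect_equal(comprehensive_csi(c(3.955, 2.561)), 6.516)
  expect_equal(comprehensive_csi(4.2), 4.2)
  expect_equal(contribution_rate(3.955, 6.516), 0.6070, tolerance = 1e-4)
  expect_equal(contribution_rate(11.484, 15.282), 0.7515, tolerance = 1e-4)
  expect_equal(contribution_rate(5, 5), 1)
  expect_error(contribution_rate(1, 0), "CSI")
})

test_that("dominance labels follow the strict 50% rule", {
  expect_equal(classify_dominance(0.6070), "temperature")
  expect_equal(classify_dominance(1 - 0.7515), "precipitation")
  expect_equal(classify_dominance(0.5), "mixed")
})

test_that("sensitivity records satisfy their identities", {
  set.seed(66)
  digests <- expand.grid(mountain_id = paste0("M", 1:6),
                         factor = impact_factors(),
                         stringsAsFactors = FALSE)
  digests$Ex <- runif(nrow(digests), 0.05, 0.5)
  digests$En <- runif(nrow(digests), 0.02, 0.2)
  digests$He <- runif(nrow(digests), 0, 0.05)
  digests$n <- 10L
  counts <- setNames(sample(50:300, 6), paste0("M", 1:6))
  rec <- sensitivity_records(digests, counts)
  expect_equal(rec$csi, rec$tsi + rec$psi, tolerance = 1e-9)
  expect_equal(rec$p_temp + rec$p_precip, rep(1, 6), tolerance = 1e-9)
  # SI is linear in Ni holding N
  rec2 <- sensitivity_records(digests, counts, N = sum(counts))
  d <- digests[digests$mountain_id == "M1" & digests$factor == "jan_temp_c", ]
  si1 <- single_factor_si(cloud(d$Ex, d$En, d$He), counts[["M1"]],
                          sum(counts))
  si2 <- single_factor_si(cloud(d$Ex, d$En, d$He), 2 * counts[["M1"]],
                          sum(counts))
  expect_equal(si2, 2 * si1, tolerance = 1e-12)
  # dominance labels do not depend on the presentation scale
  rec_raw <- sensitivity_records(digests, counts, scale = 1)
  expect_equal(rec_raw$dominance, rec$dominance)
})

test_that("published index pairs reproduce the printed summary columns", {
  tbl <- nh_mountain_indices()
  rec <- sensitivity_from_indices(tbl)
  # comprehensive column at 2-decimal precision
  expect_true(all(abs(rec$csi - tbl$csi_printed) <= 0.005))
  # contribution columns, excluding the internally inconsistent row
  consistent <- abs(tbl$p_temp_printed_pct + tbl$p_precip_printed_pct -
                      100) < 0.5
  expect_equal(sum(!consistent), 1L)  # one known misprinted row
  # within one unit of the last printed digit everywhere consistent
  expect_true(all(abs(100 * rec$p_temp - tbl$p_temp_printed_pct)[consistent]
                  <= 0.0105))
  expect_true(all(abs(100 * rec$p_precip -
                        tbl$p_precip_printed_pct)[consistent]
                  <= 0.0105))
  # spot values round exactly to the printed 2-decimal percentages
  spot <- c(Carpathians = 60.70, Daba = 69.66, `Rila-Rhodope` = 24.85,
            `Sistema Iberico` = 78.17, Alborz = 57.60, Pyrenees = 48.61)
  got <- round(100 * rec$p_temp[match(names(spot), rec$mountain_id)], 2)
  expect_equal(got, unname(spot))
})

test_that("regional summaries aggregate means and dominance fractions", {
  rec <- sensitivity_from_indices(nh_mountain_indices())
  one <- regional_summary(rec[rec$mountain_id == "Daba", , drop = FALSE],
                          "region")
  expect_equal(one$mean_csi, rec$csi[rec$mountain_id == "Daba"])

  moist <- regional_summary(rec, "moisture")
  humid <- moist[moist$moisture == "humid", ]
  arid <- moist[moist$moisture == "arid_semiarid", ]
  expect_equal(humid$n_mountains, 23L)
  expect_equal(humid$n_temp_dominated, 16L)
  expect_equal(arid$n_mountains, 5L)
  expect_equal(arid$n_precip_dominated, 4L)

  rec$region[1] <- NA
  expect_warning(regional_summary(rec, "region"), "omitted")
})

test_that("trend fits agree with the closed-form oracle", {
  lat <- seq(46, 27, length.out = 10)
  tf <- trend_vs_coordinate(3000 - 40 * lat, lat)
  expect_equal(tf$r, -1, tolerance = 1e-12)
  expect_equal(tf$r_squared, tf$r^2, tolerance = 1e-12)

  tf <- trend_vs_coordinate(rep(5, 5), 1:5)
  expect_false(tf$ok)
  expect_equal(tf$reason, "zero_value_variance")
  expect_false(trend_vs_coordinate(1:5, rep(2, 5))$ok)

  set.seed(88)
  x <- rnorm(10); y <- 2 * x + rnorm(10)
  tf <- trend_vs_coordinate(y, x)
  ref <- oracle_slope_r(x, y)
  expect_equal(tf$slope, ref$slope, tolerance = 1e-10)
  expect_equal(tf$r, ref$r, tolerance = 1e-10)
})
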