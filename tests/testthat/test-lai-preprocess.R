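test_that("monthly composites reduce to per-month maxima", {
  lat <- c(40, 50); lon <- c(0, 10)
  stamps <- data.frame(year = c(2001, 2001, 2001, 2001),
                       month = c(1, 1, 2, 2))
  vals <- array(NA_real_, c(4, 2, 2))
  vals[1, , ] <- 1.2; vals[2, , ] <- 1.5   # Jan composites
  vals[3, , ] <- 0.8; vals[4, , ] <- 0.8   # Feb: all equal
  f <- monthly_max_composite(vals, stamps, lat, lon)
  expect_equal(f$values[1, 1, 1], 1.5)
  expect_equal(f$values[2, 1, 1], 0.8)
  expect_identical(f$months, data.frame(year = c(2001L, 2001L), month = 1:2))

  # order of composites within a month is irrelevant
  g <- monthly_max_composite(vals[c(2, 1, 4, 3), , , drop = FALSE],
                             stamps, lat, lon)
  expect_identical(g$values, f$values)

  # single composite per month is the identity
  one <- monthly_max_composite(vals[c(1, 3), , , drop = FALSE],
                               data.frame(year = 2001, month = 1:2), lat, lon)
  expect_equal(one$values[1, 1, 1], 1.2)

  # a month with zero composites is an explicit error naming the month
  gap <- data.frame(year = 2001, month = c(1, 1, 3, 3))
  expect_error(monthly_max_composite(vals, gap, lat, lon), "2001-02")
})

test_that("aggregation to a coarse grid is a cosine-area-weighted mean", {
  # 2x2 children, values {1,1,3,3}: equal-latitude mean is 2
  f <- grid_field(matrix(c(1, 1, 3, 3), 2, 2), c(44.9, 45.1), c(0, 1))
  cf <- aggregate_to_grid(f, 2, 2)
  expect_equal(dim(cf$values), c(1L, 1L))
  expect_equal(cf$values[1, 1], 2, tolerance = 1e-6)

  # children at different latitudes: verify against brute-force weights
  lat <- c(30, 50); vals <- matrix(c(1, 3, 1, 3), 2, 2)
  g <- aggregate_to_grid(grid_field(vals, lat, c(0, 1)), 2, 2)
  w <- cos(lat * pi / 180)
  expect_equal(g$values[1, 1],
               sum(c(1, 3, 1, 3) * rep(w, 2)) / sum(rep(w, 2)),
               tolerance = 1e-12)

  # all-masked children yield a masked parent
  fm <- grid_field(matrix(NA_real_, 2, 2), c(44, 46), c(0, 1))
  expect_true(is.na(aggregate_to_grid(fm, 2, 2)$values[1, 1]))

  expect_error(aggregate_to_grid(f, 3, 2), "nest")
})

test_that("PFT-level LAI conserves the cell value under cover weighting", {
  lat <- c(45); lon <- c(0)
  cell <- grid_field(matrix(2.0, 1, 1), lat, lon)
  cover <- array(c(0.5, 0.5, 0), c(3, 1, 1))   # two PFTs + bare soil
  res <- pft_level_lai(cell, cover, bare_index = 3)
  expect_equal(res$pft_lai[[1]][1, 1], 2.0)
  expect_equal(res$pft_lai[[2]][1, 1], 2.0)
  expect_equal(res$pft_lai[[3]][1, 1], 0)
  expect_equal(res$reconstructed[1, 1], 2.0)

  # fractional cover {0.3, 0.2, bare 0.5}, LAI 1 -> weighted veg mean 1
  cover2 <- array(c(0.3, 0.2, 0.5), c(3, 1, 1))
  cell2 <- grid_field(matrix(1.0, 1, 1), lat, lon)
  res2 <- pft_level_lai(cell2, cover2, bare_index = 3)
  expect_equal(res2$reconstructed[1, 1], 1.0)

  # bare-soil-only cell with LAI 0 stays all-zero
  bare <- array(c(0, 0, 1), c(3, 1, 1))
  res3 <- pft_level_lai(grid_field(matrix(0, 1, 1), lat, lon), bare, 3)
  expect_true(all(vapply(res3$pft_lai, function(m) all(m == 0), logical(1))))

  # zero vegetated fraction with non-zero LAI warns and masks
  expect_warning(
    res4 <- pft_level_lai(grid_field(matrix(1.5, 1, 1), lat, lon), bare, 3),
    "zero vegetated")
  expect_true(is.na(res4$reconstructed[1, 1]))

  expect_error(pft_level_lai(cell, array(c(0.9, 0.9, 0), c(3, 1, 1)), 3),
               "more than 1")
})

test_that("scenario generator reproduces imposed trends and is seeded", {
  lat <- tiny_lat; lon <- tiny_lon
  # zero slope and noise: climatology repeated each year
  scen0 <- lai_scenario(slopes = c(JJA = 0), noise_sd = 0, seed = 5)
  f0 <- generate_lai_scenario(scen0, lat, lon, 2001:2003)
  clim <- default_lai_climatology()
  for (m in c(1, 7, 12))
    expect_equal(unique(as.vector(
      f0$values[f0$months$month == m, , ])), clim[m])

  # noiseless: OLS on the seasonal NH-mean series returns the slope exactly
  scen <- lai_scenario(noise_sd = 0, seed = 5)
  f <- generate_lai_scenario(scen, lat, lon, 1982:2014)
  jja <- seasonal_series(f, "JJA")
  nh <- area_weighted_mean(jja)
  tr <- ols_trend(nh, jja$years)
  expect_equal(tr$slope_decade, 0.046, tolerance = 1e-10)
  mam <- seasonal_series(f, "MAM")
  expect_equal(ols_trend(area_weighted_mean(mam), mam$years)$slope_decade,
               0.019, tolerance = 1e-10)

  # same seed -> identical fields; different seed -> different noise
  scen_n <- lai_scenario(noise_sd = 0.15, seed = 42)
  a <- generate_lai_scenario(scen_n, lat, lon, 2001:2004)
  b <- generate_lai_scenario(scen_n, lat, lon, 2001:2004)
  expect_identical(a$values, b$values)
  scen_m <- lai_scenario(noise_sd = 0.15, seed = 43)
  expect_false(identical(
    generate_lai_scenario(scen_m, lat, lon, 2001:2004)$values, a$values))

  # generated LAI is clipped at zero
  wild <- lai_scenario(noise_sd = 3, seed = 2)
  g <- generate_lai_scenario(wild, lat, lon, 2001:2002)
  expect_true(all(g$values >= 0))
  expect_gt(attr(g, "n_clipped"), 0)
})

test_that("imposed slope is recovered within 2 SE at realistic noise", {
  # stochastic property: over many seeded replicates the 2-SE interval
  # around the fitted JJA trend should cover the imposed slope ~95% often
  hits <- 0L
  n_rep <- 60L
  for (k in seq_len(n_rep)) {
    scen <- lai_scenario(noise_sd = 0.15, seed = 7000 + k)
    f <- generate_lai_scenario(scen, tiny_lat, tiny_lon, 1982:2014)
    jja <- seasonal_series(f, "JJA")
    tr <- ols_trend(area_weighted_mean(jja), jja$years)
    if (abs(tr$slope_decade - 0.046) <= 2 * tr$se_decade) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})
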