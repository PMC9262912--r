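test_that("OLS trend is exact on noiseless lines and agrees with lm", {
  years <- 1982:2014
  # perfect line 0.1 K/yr -> 1.0 K/decade, zero SE, strongest class
  tr <- ols_trend(0.1 * (years - 1982), years)
  expect_equal(tr$slope_decade, 1.0, tolerance = 1e-12)
  expect_equal(tr$se_decade, 0)
  expect_identical(tr$stars, "***")
  # constant series: zero slope, p treated as 1
  trc <- ols_trend(rep(2.5, 33), years)
  expect_equal(trc$slope_decade, 0)
  expect_equal(trc$p_value, 1)
  expect_identical(trc$stars, "n.s.")
  # independent oracle: stats::lm on noisy data
  set.seed(10)
  y <- 0.03 * (years - 2000) + rnorm(33, sd = 0.5)
  fit <- summary(stats::lm(y ~ years))$coefficients
  tr2 <- ols_trend(y, years)
  expect_equal(tr2$slope_decade, unname(fit["years", "Estimate"]) * 10,
               tolerance = 1e-10)
  expect_equal(tr2$se_decade, unname(fit["years", "Std. Error"]) * 10,
               tolerance = 1e-10)
  expect_equal(tr2$p_value, unname(fit["years", "Pr(>|t|)"]), tolerance = 1e-10)
  expect_error(ols_trend(c(1, 2), c(2000, 2001)), "at least 3")
})

test_that("gridded trend maps match the per-cell scalar estimator", {
  set.seed(4)
  years <- 1991:2010
  vals <- array(rnorm(20 * 3 * 4), c(20, 3, 4))
  vals[, 2, 2] <- 0.05 * (years - 2000) + rnorm(20, sd = 0.1)
  af <- annual_field(vals, c(40, 50, 60), c(0, 10, 20, 30), years)
  tm <- trend_map(af)
  for (i in 1:3) for (j in 1:4) {
    ref <- ols_trend(vals[, i, j], years)
    expect_equal(tm$slope_decade[i, j], ref$slope_decade, tolerance = 1e-10)
    expect_equal(tm$se_decade[i, j], ref$se_decade, tolerance = 1e-10)
    expect_equal(tm$p_value[i, j], ref$p_value, tolerance = 1e-10)
  }
  # missing years mask the cell
  vals[3, 1, 1] <- NA
  tm2 <- trend_map(annual_field(vals, c(40, 50, 60), c(0, 10, 20, 30), years))
  expect_true(is.na(tm2$slope_decade[1, 1]))
})

test_that("seasonal temperature amplitude is July minus January", {
  st <- month_stamps(2001:2002)
  ta <- rep(0, 24)
  ta[st$month == 7] <- 273.15 + 15
  ta[st$month == 1] <- 273.15 - 10
  amp <- sat_amplitude(ta, st)
  expect_equal(as.numeric(amp), c(25, 25))
  expect_identical(attr(amp, "years"), 2001:2002)
  # identical July and January: zero amplitude
  expect_equal(as.numeric(sat_amplitude(rep(280, 24), st)), c(0, 0))
  # antisymmetry under swapping the two months
  ta_swap <- ta
  ta_swap[st$month == 7] <- 273.15 - 10
  ta_swap[st$month == 1] <- 273.15 + 15
  expect_equal(as.numeric(sat_amplitude(ta_swap, st)),
               -as.numeric(sat_amplitude(ta, st)))
  # warmer-winter / cooler-summer drift gives a negative amplitude trend,
  # checked against brute-force recomputation
  years <- 1982:2014
  stl <- month_stamps(years)
  drift <- numeric(nrow(stl))
  drift[stl$month == 7] <- 290 - 0.02 * (stl$year[stl$month == 7] - 1982)
  drift[stl$month == 1] <- 260 + 0.03 * (stl$year[stl$month == 1] - 1982)
  amp2 <- sat_amplitude(drift, stl)
  tr <- ols_trend(as.numeric(amp2), attr(amp2, "years"))
  expect_equal(tr$slope_decade, -0.5, tolerance = 1e-10)
  brute <- vapply(years, function(y)
    drift[stl$year == y & stl$month == 7] - drift[stl$year == y & stl$month == 1],
    numeric(1))
  expect_equal(as.numeric(amp2), brute)
  # gridded input yields a per-cell annual field
  f <- tiny_monthly_field(2001:2002, fill = 1)
  gamp <- sat_amplitude(f)
  expect_s3_class(gamp, "annual_field")
  expect_true(all(gamp$values == 0))
})

test_that("correlation handles exact dependence and detrending", {
  x <- c(1, 3, 2, 5, 4, 6, 8, 7)
  r <- lai_delta_correlation(x, -x)
  expect_equal(r$r, -1, tolerance = 1e-12)
  # a shared linear trend fakes correlation; detrending removes it
  set.seed(8)
  years <- 1:40
  x2 <- 0.5 * years + rnorm(40, sd = 0.3)
  y2 <- 0.5 * years + rnorm(40, sd = 0.3)
  raw <- lai_delta_correlation(x2, y2, years)
  det <- lai_delta_correlation(x2, y2, years, detrend = TRUE)
  expect_gt(raw$r, 0.9)
  expect_lt(abs(det$r), 0.35)
  expect_error(lai_delta_correlation(1:4, 1:5), "lengths differ")
})

test_that("phase-space marginals recover planted linear structure", {
  set.seed(12)
  n <- 40
  sm <- matrix(rnorm(n * n), n, n)
  z <- matrix(rnorm(n * n), n, n)
  # response exactly equal to one driver: marginal is the identity line
  ps <- phase_space_summary(z, sm, z, bins = 10, min_count = 3)
  fit <- stats::lm(mean ~ center, data = ps$marginal_y)
  expect_equal(unname(coef(fit)["center"]), 1, tolerance = 0.05)
  # uniform response: flat surface and flat marginals
  ps0 <- phase_space_summary(matrix(2, n, n), sm, z, bins = 8)
  expect_true(all(abs(ps0$surface - 2) < 1e-12, na.rm = TRUE))
  expect_true(all(abs(ps0$marginal_x$mean - 2) < 1e-12))
})

test_that("latitudinal profiles are banded area-weighted means", {
  lat <- c(32, 38, 62, 68)
  m <- matrix(1, 4, 3)
  prof <- latitudinal_profile(m, lat, band_width_deg = 10)
  expect_true(all(abs(prof$mean - 1) < 1e-12))
  # nonzero only in the 60-70 band stays in that band
  m2 <- matrix(0, 4, 3); m2[3:4, ] <- 5
  prof2 <- latitudinal_profile(m2, lat, band_width_deg = 10)
  expect_equal(prof2$mean[prof2$lat_lo == 60], 5)
  expect_equal(prof2$mean[prof2$lat_lo == 30], 0)
  # hand computation: two cells sharing one band mix with cosine weights
  lat3 <- c(52, 58)
  m3 <- matrix(c(1, 3), 2, 1)
  prof3 <- latitudinal_profile(m3, lat3, band_width_deg = 10)
  expect_identical(nrow(prof3), 1L)
  expect_equal(prof3$mean,
               sum(c(1, 3) * cos(lat3 * pi / 180)) / sum(cos(lat3 * pi / 180)),
               tolerance = 1e-12)
})

test_that("stippling marks significant cells and reports the fraction", {
  # perfect linear trends in every cell: all stippled
  years <- 2001:2015
  vals <- array(rep(0.1 * (years - 2001), 6), c(15, 2, 3))
  tm <- trend_map(annual_field(vals, c(40, 50), c(0, 10, 20), years))
  sm <- stipple_mask(tm$p_value, alpha = 0.05)
  expect_true(all(sm))
  expect_equal(attr(sm, "fraction"), 1)
  # alpha = 0 stipples nothing
  sm0 <- stipple_mask(tm$p_value, alpha = 0)
  expect_false(any(sm0))
  expect_equal(attr(sm0, "fraction"), 0)
  # land mask restricts the denominator
  land <- matrix(c(TRUE, FALSE), 2, 3)
  sml <- stipple_mask(tm$p_value, alpha = 0.05, mask = land)
  expect_equal(sum(sml), sum(land))
})
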