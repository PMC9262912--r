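test_that("redistribution factors match hand-evaluated definitions", {
  p <- sim_params()
  # f_s = rho*Cp/r_a + 4 eps_s sigma T_s^3 at T_s = 288.15 K, r_a = 50
  fs <- redistribution_factor_fs(288.15, 50, p)
  expect_equal(fs, 1.205 * 1013 / 50 + 4 * 0.95 * 5.67e-8 * 288.15^3,
               tolerance = 1e-12)
  expect_equal(fs, 29.57, tolerance = 0.01)
  # f_a with eps_a = 0.8
  fa <- redistribution_factor_fa(288.15, 50, 0.8, p)
  expect_equal(fa, 1.205 * 1013 / 50 + 0.8 * 4 * 0.95 * 5.67e-8 * 288.15^3,
               tolerance = 1e-12)
  expect_equal(fa, 28.54, tolerance = 0.01)
  # r_a -> Inf leaves only the longwave sensitivity
  expect_equal(redistribution_factor_fs(288.15, Inf, p),
               4 * 0.95 * 5.67e-8 * 288.15^3, tolerance = 1e-12)
  # identity at eps_a = 1, ordering below it
  t_s <- seq(250, 310, by = 5); r_a <- seq(20, 200, length.out = 13)
  expect_identical(redistribution_factor_fa(t_s, r_a, 1, p),
                   redistribution_factor_fs(t_s, r_a, p))
  for (ea in c(0, 0.3, 0.9))
    expect_true(all(redistribution_factor_fa(t_s, r_a, ea, p) <=
                      redistribution_factor_fs(t_s, r_a, p)))
  expect_error(redistribution_factor_fs(-1, 50), "positive")
  expect_error(redistribution_factor_fa(288, 50, 1.2), "\\[0, 1\\]")
})

test_that("forcing components carry the conventional signs and zeros", {
  p <- sim_params()
  base <- list(s_dn = 200, albedo = 0.2, r_a = 50, t_s = 290, t_a = 288)
  # albedo brightening by +0.01 is a -2 W m-2 forcing
  d1 <- list(alpha = 0.01, s_dn = 0, le = 0, r_a = 0, eps_a = 0)
  expect_equal(forcing_components(base, d1, p)$F_alpha, -2.0)
  # emissivity +0.01 at T_a = 280 K: +3.31 W m-2
  base2 <- list(s_dn = 200, albedo = 0.2, r_a = 50, t_s = 282, t_a = 280)
  d2 <- list(alpha = 0, s_dn = 0, le = 0, r_a = 0, eps_a = 0.01)
  expect_equal(forcing_components(base2, d2, p)$F_eps,
               0.95 * 5.67e-8 * 280^4 * 0.01, tolerance = 1e-12)
  expect_equal(forcing_components(base2, d2, p)$F_eps, 3.31, tolerance = 0.01)
  # greening-like deltas produce the mechanism signs
  dg <- list(alpha = -0.01, s_dn = 0, le = 5, r_a = -5, eps_a = 0.005)
  fc <- forcing_components(base, dg, p)
  expect_gt(fc$F_alpha, 0)   # darkening warms
  expect_lt(fc$F_le, 0)      # more evapotranspiration cools
  expect_gt(fc$F_eps, 0)     # water-vapor feedback warms
  # all-zero deltas give identically zero components
  d0 <- list(alpha = 0, s_dn = 0, le = 0, r_a = 0, eps_a = 0)
  expect_true(all(unlist(forcing_components(base, d0, p)) == 0))
})

test_that("radiative/non-radiative grouping sums exactly", {
  p <- sim_params()
  # components (alpha, Sdn, le, ra, eps) = (-2, +1, -5, +0.5, +3)
  fc <- structure(list(F_alpha = -2, F_sdn = 1, F_le = -5, F_ra = 0.5,
                       F_eps = 3), class = "forcing_components")
  g <- group_r_nr(fc)
  expect_equal(g$R, 2)
  expect_equal(g$NR, -4.5)
  expect_equal(g$All, -2.5)
  expect_equal(g$All, with(fc, F_alpha + F_sdn + F_le + F_ra + F_eps),
               tolerance = 1e-12)
  zero <- structure(list(F_alpha = 0, F_sdn = 0, F_le = 0, F_ra = 0,
                         F_eps = 0), class = "forcing_components")
  expect_true(all(unlist(group_r_nr(zero)) == 0))
})

test_that("first-order dT_s formula divides forcing by f_s", {
  p <- sim_params()
  base <- list(s_dn = 200, albedo = 0.2, r_a = 50, t_s = 288.15, t_a = 288.15,
               eps_a = 0.8)
  fc <- structure(list(F_alpha = -2, F_sdn = 0, F_le = 0, F_ra = 0, F_eps = 0),
                  class = "forcing_components")
  fs <- redistribution_factor_fs(288.15, 50, p)
  # with dT_a = 0: dT_s = sum(F)/f_s
  expect_equal(decompose_delta_ts(fc, 0, base, params = p), -2 / fs,
               tolerance = 1e-12)
  expect_equal(-2 / fs, -0.0676, tolerance = 1e-3)
  # with zero forcing, eps_a = 1 and T_a = T_s the coefficient collapses to 1
  base1 <- list(s_dn = 200, albedo = 0.2, r_a = 50, t_s = 288, t_a = 288,
                eps_a = 1)
  f0 <- structure(list(F_alpha = 0, F_sdn = 0, F_le = 0, F_ra = 0, F_eps = 0),
                  class = "forcing_components")
  expect_equal(decompose_delta_ts(f0, 0.37, base1, params = p), 0.37,
               tolerance = 1e-12)
  # linearity: doubling all inputs doubles the prediction
  fc2 <- structure(lapply(unclass(fc), `*`, 2), class = "forcing_components")
  expect_equal(decompose_delta_ts(fc2, 0.2, base, params = p),
               2 * decompose_delta_ts(fc, 0.1, base, params = p),
               tolerance = 1e-12)
  # the two T^3 coefficient variants agree when T_a = T_s
  expect_equal(decompose_delta_ts(fc, 0.1, base, ta_coef = "air", params = p),
               decompose_delta_ts(fc, 0.1, base, ta_coef = "surface", params = p),
               tolerance = 1e-12)
})

test_that("air-temperature attribution reconstructs exactly", {
  p <- sim_params()
  fc <- structure(list(F_alpha = 1.5, F_sdn = -0.5, F_le = -4, F_ra = 0.25,
                       F_eps = 2), class = "forcing_components")
  fa <- redistribution_factor_fa(285, 60, 0.85, p)
  # residual-free case: actual equals sum(F)/f_a
  tot <- Reduce(`+`, unclass(fc))
  dec <- decompose_delta_ta(tot / fa, fc, fa)
  expect_equal(dec$cir, 0, tolerance = 1e-15)
  # zero forcing: everything is circulation
  zero <- structure(lapply(unclass(fc), `*`, 0), class = "forcing_components")
  dec0 <- decompose_delta_ta(0.42, zero, fa)
  expect_equal(dec0$cir, 0.42)
  expect_equal(dec0$rad, 0)
  # per-component contributions sum to the radiative part
  expect_equal(Reduce(`+`, dec$per_component), dec$rad, tolerance = 1e-15)
  expect_error(decompose_delta_ta(0.1, fc, -3), "> 0")
})

test_that("linearisation error decays quadratically with perturbation size", {
  res <- closure_convergence_study(c(0.02, 0.01), years = 2001:2003,
                                   lat = seq(35, 55, by = 10),
                                   lon = seq(0, 90, by = 30))
  expect_gt(res$ratio[2], 3.5)
  expect_lt(res$max_err[2], res$max_err[1])
})

test_that("experiment decomposition is exact and first-order faithful", {
  ex <- tiny_experiment(members = 2, years = 2001:2004)
  dec <- decompose_experiment(ex$set, "JJA")
  # exact reconstruction everywhere
  expect_lt(max(abs(dec$decomposed$rad + dec$decomposed$cir - dec$d_ta)), 1e-12)
  # grouping identity everywhere
  g <- dec$groups
  expect_lt(max(abs(g$R + g$NR - g$All)), 1e-12)
  comp_sum <- Reduce(`+`, unclass(dec$components))
  expect_lt(max(abs(comp_sum - g$All)), 1e-12)
  # the first-order dT_s prediction tracks the simulated difference
  expect_lt(max(abs(dec$d_ts_pred - dec$d_ts)), 0.05)
  # climatology baseline variant runs and keeps the identities
  dec2 <- decompose_experiment(ex$set, "JJA", baseline = "climatology")
  expect_lt(max(abs(dec2$decomposed$rad + dec2$decomposed$cir - dec2$d_ta)),
            1e-12)
})
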