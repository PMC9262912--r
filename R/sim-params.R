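#' Parameters of the toy land-atmosphere column model
#'
#' Physical constants follow the surface-energy-balance convention used
#' throughout the package: land-surface emissivity 0.95,
#' Stefan-Boltzmann constant 5.67e-8 W m-2 K-4, air density
#' 1.205 kg m-3 and specific heat of air 1013 J kg-1 K-1. All other
#' parameters shape the invented closure forms of the toy model
#' (exponential canopy masking of albedo, bulk aerodynamic resistance,
#' bucket hydrology, AR(1) circulation proxy, humidity-driven air
#' emissivity) and are tunable.
#'
#' @param ... named overrides of any default listed below.
#' @return an object of class `sim_params` (a named list).
#'
#' @details Defaults:
#' \describe{
#'   \item{eps_s, sigma, rho, cp}{energy-balance constants (see above).}
#'   \item{alpha_canopy, alpha_ground, alpha_snow, k_ext}{dense-canopy,
#'     bare-ground and snow albedos, and the canopy extinction
#'     coefficient of the exponential masking law.}
#'   \item{ra0, c_ra}{aerodynamic resistance at zero LAI (s m-1) and
#'     its LAI sensitivity: `r_a = ra0 / (1 + c_ra * lai)`.}
#'   \item{beta_max, k_et, sm_crit, soil_evap, gamma_psy}{evaporative
#'     fraction ceiling, canopy light/activity extinction, soil-moisture
#'     stress point (bucket fraction), bare-soil evaporative fraction,
#'     and psychrometric constant (kPa K-1) of the
#'     temperature-efficiency factor `s(T)/(s(T)+gamma_psy)`.}
#'   \item{capacity_mm, runoff_coef, sec_month, lambda_v}{bucket
#'     capacity (mm), linear runoff coefficient (per month), seconds per
#'     month, latent heat of vaporisation (J kg-1).}
#'   \item{w_air, b_z500}{surface-air coupling weight in
#'     `T_a = w*T_s + (1-w)*T_a_bg + b*z500`, and the circulation-proxy
#'     coupling (K m-1).}
#'   \item{eps_a_base, c_eps, q_rate, le_scale, eps_a_max}{dry-baseline
#'     air emissivity, its sensitivity to the humidity index, the
#'     exponential-memory rate of the humidity index, the latent-heat
#'     scale (W m-2) normalising it, and the emissivity cap.}
#'   \item{z_phi, z_sd}{AR(1) coefficient and innovation SD (m) of the
#'     internal-variability part of the circulation proxy.}
#'   \item{z_phi_c, z_gamma, le_ref}{persistence and forcing
#'     sensitivity (m per W m-2) of the slow, surface-driven part of
#'     the circulation proxy, nudged by the domain-mean latent-heat
#'     anomaly relative to `le_ref` (W m-2); its multi-month memory is
#'     what carries growing-season energy perturbations into later
#'     seasons.}
#'   \item{c_sw}{fractional shortwave dimming per unit humidity index
#'     (a minimal cloud/vapor shading term).}
#'   \item{tol_f, tol_t, max_iter}{Newton tolerances (W m-2, K) and
#'     iteration cap of the surface-temperature solver.}
#' }
#' @export
sim_params <- function(...) {
  p <- list(
    eps_s = 0.95, sigma = 5.67e-8, rho = 1.205, cp = 1013,
    alpha_canopy = 0.15, alpha_ground = 0.30, alpha_snow = 0.70, k_ext = 0.5,
    ra0 = 100, c_ra = 0.25,
    beta_max = 0.75, k_et = 0.5, sm_crit = 0.4, soil_evap = 0.05,
    gamma_psy = 0.066,
    capacity_mm = 150, runoff_coef = 0.15, sec_month = 2.63e6, lambda_v = 2.5e6,
    w_air = 0.5, b_z500 = 0.1,
    eps_a_base = 0.72, c_eps = 0.10, q_rate = 0.5, le_scale = 100,
    eps_a_max = 0.995,
    z_phi = 0.7, z_sd = 8, z_phi_c = 0.92, z_gamma = 0.05, le_ref = 40,
    c_sw = 0.05,
    tol_f = 1e-4, tol_t = 1e-6, max_iter = 50L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown sim_params: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    p[names(over)] <- over
  }
  stopifnot(p$eps_s > 0, p$sigma > 0, p$rho > 0, p$cp > 0, p$ra0 > 0,
            p$capacity_mm > 0, p$z_phi >= 0, p$z_phi < 1,
            p$z_phi_c >= 0, p$z_phi_c < 1)
  structure(p, class = "sim_params")
}

#' Prescribed monthly forcing cycles for the toy simulator
#'
#' Builds latitude-by-month tables of clear-sky downward shortwave
#' radiation, background (advected) air temperature, and precipitation.
#' The shortwave cycle follows a solar-declination proxy; the background
#' temperature combines a meridional gradient with a seasonal cycle
#' whose amplitude grows poleward. Two hydrological regimes are
#' provided: `"wet"` (ample year-round precipitation, soil-moisture
#' stress inactive) and `"moisture_limited"` (dry summers, so spring
#' evapotranspiration draws down the bucket that summer depends on).
#'
#' @param lat cell-centre latitudes (degrees north).
#' @param regime `"wet"` or `"moisture_limited"`.
#' @param ta_trend length-12 numeric, imposed background air-temperature
#'   trend per calendar month (K per decade); default none.
#' @return a `sim_forcing` list with `[12 x nlat]` matrices `sdn`,
#'   `ta_bg`, `precip`, the per-month trend vector, and the regime tag.
#' @export
default_forcing <- function(lat, regime = c("wet", "moisture_limited"),
                            ta_trend = rep(0, 12)) {
  regime <- match.arg(regime)
  stopifnot(length(ta_trend) == 12L)
  m <- 1:12
  decl <- 23.44 * cos(pi * (m - 6.5) / 6)          # solar declination proxy
  mu <- outer(decl, lat, function(d, phi) cos((phi - d) * pi / 180))
  sdn <- pmax(480 * mu * 0.6, 10)
  amp <- 8 + 0.25 * (lat - 25)
  ta_bg <- outer(m, lat, function(mm, phi) 288 - 0.55 * (phi - 25)) +
    outer(cos(2 * pi * (m - 7) / 12), amp)
  precip <- if (regime == "wet") {
    matrix(95, 12, length(lat))
  } else {
    matrix(c(55, 52, 48, 38, 26, 16, 12, 12, 22, 35, 45, 52), 12, length(lat))
  }
  structure(list(sdn = sdn, ta_bg = ta_bg, precip = precip,
                 ta_trend = as.numeric(ta_trend), regime = regime),
            class = "sim_forcing")
}

#' Prescribed snow-cover table
#'
#' Snow is prescribed, not prognostic: the toy model only needs the
#' snow-on versus snow-off albedo contrast during the cold and shoulder
#' seasons. A cell is snow-covered in November-March above 45 deg N, in
#' April and October above 60 deg N, and in May above 75 deg N.
#'
#' @param lat cell-centre latitudes.
#' @return logical `[12 x nlat]` matrix, `TRUE` where snow-covered.
#' @export
default_snow_table <- function(lat) {
  snow <- matrix(FALSE, 12, length(lat))
  for (m in 1:12) {
    thr <- if (m %in% c(11, 12, 1, 2, 3)) 45 else if (m %in% c(4, 10)) 60 else
      if (m == 5) 75 else Inf
    snow[m, ] <- lat >= thr
  }
  snow
}

#' Longitudinal weighting pattern of the circulation proxy
#'
#' The member-shared AR(1) circulation index is projected onto the grid
#' through a fixed stationary-wave-like pattern so that the
#' geopotential-height proxy varies across cells.
#'
#' @param lat,lon grid axes.
#' @return `[nlat x nlon]` matrix of weights with mean ~1.
#' @export
z500_pattern <- function(lat, lon) {
  outer(rep(1, length(lat)), 1 + 0.75 * sin(lon * pi / 60)) *
    matrix(1 + 0.2 * cos((lat - 55) * pi / 35), length(lat), length(lon))
}
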