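#' Surface albedo from LAI (exponential canopy masking)
#'
#' `alpha = alpha_canopy + (alpha_background - alpha_canopy) *
#' exp(-k_ext * lai)`, where the background is bare ground or, when the
#' cell is snow-covered, snow. Albedo decreases strictly with LAI
#' whenever the background is brighter than the canopy — the masking
#' effect of darker canopies over bright ground or snow.
#'
#' @param lai leaf area index (m2 m-2), vectorised.
#' @param snow logical, snow-covered background.
#' @param params a [sim_params()].
#' @return albedo in (0, 1).
#' @export
albedo_from_lai <- function(lai, snow = FALSE, params = sim_params()) {
  if (any(lai < 0, na.rm = TRUE)) stop("lai must be >= 0", call. = FALSE)
  bg <- ifelse(snow, params$alpha_snow, params$alpha_ground)
  params$alpha_canopy + (bg - params$alpha_canopy) * exp(-params$k_ext * lai)
}

#' Aerodynamic resistance from LAI
#'
#' `r_a = ra0 / (1 + c_ra * lai)`: taller/denser canopies are
#' aerodynamically rougher, so turbulent transfer becomes more
#' efficient (resistance drops) as LAI rises.
#'
#' @inheritParams albedo_from_lai
#' @return aerodynamic resistance (s m-1), strictly positive.
#' @export
aerodynamic_resistance_from_lai <- function(lai, params = sim_params()) {
  if (any(lai < 0, na.rm = TRUE)) stop("lai must be >= 0", call. = FALSE)
  params$ra0 / (1 + params$c_ra * lai)
}

#' Slope of the saturation vapour pressure curve
#' @param t_k temperature (K).
#' @return slope (kPa per K), Clausius-Clapeyron (Tetens form).
#' @keywords internal
svp_slope <- function(t_k) {
  tc <- t_k - 273.15
  4098 * 0.6108 * exp(17.27 * tc / (tc + 237.3)) / (tc + 237.3)^2
}

#' Evaporative fraction and transpiration share
#'
#' The fraction `beta` of available surface energy dissipated as latent
#' heat combines canopy activity `1 - exp(-k_et * lai * v)` (with `v`
#' the vegetation-activity switch, 0 under snow), a linear-ramp
#' soil-moisture stress `min(1, SM / sm_crit)`, and a
#' temperature-efficiency factor `s(T)/(s(T) + gamma_psy)` expressing
#' that vaporisation is a more effective cooling pathway at higher
#' temperatures. A small bare-soil evaporation term (`soil_evap`) is
#' added. The transpiration share of total evapotranspiration is
#' `1 - exp(-k_et * lai * v)`, returning 0 for unvegetated or dormant
#' cells.
#'
#' @param lai leaf area index (m2 m-2).
#' @param sm soil moisture as a fraction of bucket capacity, in \[0, 1\].
#' @param t_ref reference temperature (K) for the efficiency factor.
#' @param snow logical vegetation-dormancy switch (snow-covered).
#' @param params a [sim_params()].
#' @return list with `beta` (in \[0, 1)) and `t_share` (T/ET, in \[0, 1)).
#' @export
evaporative_fraction <- function(lai, sm, t_ref, snow = FALSE,
                                 params = sim_params()) {
  if (any(sm < 0 | sm > 1, na.rm = TRUE)) stop("sm must lie in [0, 1]", call. = FALSE)
  v <- ifelse(snow, 0, 1)
  act <- 1 - exp(-params$k_et * lai * v)
  stress <- pmin(1, sm / params$sm_crit)
  s <- svp_slope(t_ref)
  tf <- s / (s + params$gamma_psy)
  beta <- pmin(params$beta_max * act * stress * tf +
                 params$soil_evap * stress * tf, 0.95)
  list(beta = beta, t_share = act)
}

#' Newton solver for the surface energy balance
#'
#' Solves `S_dn (1 - alpha) + eps_s sigma (eps_a T_a^4 - T_s^4)
#' - rho C_p (T_s - T_a) / r_a - lambda_E(T_s) = 0` for `T_s`, with
#' `lambda_E = beta * max(0, S_net + L_net)` and the ground heat flux
#' neglected. All arguments are vectorised over cells. Convergence
#' requires both `|F| < tol_f` (W m-2) and `|dT_s| < tol_t` (K).
#'
#' @param s_dn downward shortwave (W m-2).
#' @param alpha surface albedo.
#' @param eps_a air longwave emissivity.
#' @param t_a near-surface air temperature (K).
#' @param r_a aerodynamic resistance (s m-1); may be `Inf`.
#' @param beta evaporative fraction.
#' @param params a [sim_params()].
#' @param t_init initial guess for `T_s` (default `t_a`).
#' @return list with `t_s`, `le`, `h`, `s_net`, `l_net`, `residual`,
#'   `iterations`.
#' @export
solve_surface_temperature <- function(s_dn, alpha, eps_a, t_a, r_a, beta,
                                      params = sim_params(), t_init = t_a) {
  es <- params$eps_s; sg <- params$sigma
  cond <- ifelse(is.finite(r_a), params$rho * params$cp / r_a, 0)
  ts <- t_init
  n <- max(length(s_dn), length(t_a), length(ts))
  ts <- rep_len(ts, n)
  f_of <- function(ts) {
    a_avail <- s_dn * (1 - alpha) + es * sg * (eps_a * t_a^4 - ts^4)
    le <- beta * pmax(0, a_avail)
    h <- cond * (ts - t_a)
    list(f = a_avail - h - le, a = a_avail, le = le, h = h)
  }
  it <- 0L
  repeat {
    it <- it + 1L
    st <- f_of(ts)
    dfdt <- -4 * es * sg * ts^3 * (1 - beta * (st$a > 0)) - cond
    step <- st$f / dfdt
    ts_new <- ts - step
    conv <- max(abs(st$f)) < params$tol_f && max(abs(step)) < params$tol_t
    ts <- ts_new
    if (conv) break
    if (it >= params$max_iter)
      stop(sprintf(
        "surface-temperature solver failed to converge in %d iterations (max residual %.3g W m-2)",
        params$max_iter, max(abs(st$f))), call. = FALSE)
  }
  st <- f_of(ts)
  list(t_s = ts, le = st$le, h = st$h,
       s_net = s_dn * (1 - alpha),
       l_net = es * sg * (eps_a * t_a^4 - ts^4),
       residual = st$f, iterations = it)
}

# Coupled variant used by the time stepper: air temperature is the linear
# blend ta = w * ts + c0 (c0 collects background and circulation terms), so
# the pair (ts, ta) is solved jointly by Newton and the accepted state closes
# the energy balance with the final air temperature exactly.
solve_coupled_surface <- function(s_dn, alpha, eps_a, c0, r_a, beta,
                                  params, t_init) {
  es <- params$eps_s; sg <- params$sigma; w <- params$w_air
  cond <- ifelse(is.finite(r_a), params$rho * params$cp / r_a, 0)
  ts <- t_init
  f_of <- function(ts) {
    ta <- w * ts + c0
    a_avail <- s_dn * (1 - alpha) + es * sg * (eps_a * ta^4 - ts^4)
    le <- beta * pmax(0, a_avail)
    h <- cond * (ts - ta)
    list(f = a_avail - h - le, a = a_avail, le = le, h = h, ta = ta)
  }
  it <- 0L
  repeat {
    it <- it + 1L
    st <- f_of(ts)
    da <- es * sg * (4 * eps_a * st$ta^3 * w - 4 * ts^3)
    dfdt <- da * (1 - beta * (st$a > 0)) - cond * (1 - w)
    step <- st$f / dfdt
    ts_new <- ts - step
    conv <- max(abs(st$f)) < params$tol_f && max(abs(step)) < params$tol_t
    ts <- ts_new
    if (conv) break
    if (it >= params$max_iter)
      stop(sprintf(
        "coupled surface-air solver failed to converge in %d iterations (max residual %.3g W m-2)",
        params$max_iter, max(abs(st$f))), call. = FALSE)
  }
  st <- f_of(ts)
  list(t_s = ts, t_a = st$ta, le = st$le, h = st$h,
       s_net = s_dn * (1 - alpha),
       l_net = es * sg * (eps_a * st$ta^4 - ts^4),
       residual = st$f, iterations = it)
}

#' One monthly step of the bucket soil-moisture model
#'
#' Water available this month is the stored water plus precipitation;
#' evaporation (converted from the latent heat flux) draws it down but
#' cannot exceed it; storage above capacity leaves as overflow, and a
#' linear fraction of the remaining store leaves as baseflow runoff.
#' The budget `precip - evap - runoff = dSM * capacity` closes exactly
#' by construction.
#'
#' @param sm soil moisture (fraction of capacity, in \[0, 1\]).
#' @param precip_mm precipitation (mm per month), non-negative.
#' @param le latent heat flux (W m-2) demanded by the energy balance.
#' @param params a [sim_params()].
#' @return list with `sm` (updated fraction), `evap_mm` (realised
#'   evaporation) and `runoff_mm` (overflow + baseflow).
#' @export
step_soil_moisture <- function(sm, precip_mm, le, params = sim_params()) {
  if (any(precip_mm < 0, na.rm = TRUE)) stop("precipitation must be >= 0", call. = FALSE)
  if (any(sm < 0 | sm > 1, na.rm = TRUE)) stop("sm must lie in [0, 1]", call. = FALSE)
  cap <- params$capacity_mm
  demand_mm <- le * params$sec_month / params$lambda_v
  water <- sm * cap + precip_mm
  evap <- pmin(demand_mm, water)
  after <- water - evap
  overflow <- pmax(0, after - cap)
  stored <- after - overflow
  baseflow <- params$runoff_coef * stored
  list(sm = (stored - baseflow) / cap,
       evap_mm = evap,
       runoff_mm = overflow + baseflow)
}

#' Air temperature and air emissivity update
#'
#' Near-surface air temperature is a convex blend of the local surface
#' temperature and the advected background, shifted by the circulation
#' proxy: `T_a = w T_s + (1 - w) T_a_bg + b z500`. Air emissivity rises
#' with the humidity index `q` (an exponentially weighted memory of
#' past latent heat release, the water-vapor feedback pathway):
#' `eps_a = min(eps_a_base + c_eps * q, eps_a_max)`.
#'
#' @param t_s surface temperature (K).
#' @param t_a_bg background air temperature (K).
#' @param z500_anom circulation-proxy anomaly (m).
#' @param q humidity index (dimensionless, >= 0).
#' @param params a [sim_params()].
#' @return list with `t_a` and `eps_a`.
#' @export
air_temperature_update <- function(t_s, t_a_bg, z500_anom, q = 0,
                                   params = sim_params()) {
  eps_a <- pmin(params$eps_a_base + params$c_eps * pmax(q, 0), params$eps_a_max)
  t_a <- params$w_air * t_s + (1 - params$w_air) * t_a_bg +
    params$b_z500 * z500_anom
  list(t_a = t_a, eps_a = eps_a)
}
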