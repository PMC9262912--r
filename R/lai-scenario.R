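#' LAI trend scenario
#'
#' Describes a synthetic multi-year monthly LAI record with
#' season-specific linear trends superimposed on a fixed monthly
#' climatology, plus cell-level white noise. The default per-season
#' slopes are the observed Northern-Hemisphere greening rates over
#' 1982-2014 (JJA 0.046, SON 0.027, MAM 0.019 m2 m-2 per decade; DJF
#' treated as trendless), so the default scenario reproduces the
#' satellite record's seasonal ordering of greening.
#'
#' @param slopes named numeric vector of per-season LAI trends
#'   (m2 m-2 per decade) with names in MAM/JJA/SON/DJF.
#' @param climatology either a length-12 numeric vector of NH-typical
#'   monthly LAI, or a `[12 x nlat x nlon]` array; the default is a
#'   smooth seasonal cycle peaking in July.
#' @param noise_sd standard deviation of cell-level white noise
#'   (m2 m-2), applied per cell and month.
#' @param pattern spatial weighting of the trend; `NULL` means uniform
#'   (weight 1 everywhere), otherwise a `[nlat x nlon]` matrix whose
#'   area-weighted mean should be ~1 if hemispheric-mean trends are to
#'   equal the nominal slopes.
#' @param seed integer seed making the generated record reproducible.
#' @return an object of class `lai_scenario`.
#' @export
lai_scenario <- function(slopes = c(MAM = 0.019, JJA = 0.046, SON = 0.027, DJF = 0),
                         climatology = default_lai_climatology(),
                         noise_sd = 0.15, pattern = NULL, seed = 1L) {
  stopifnot(all(names(slopes) %in% SEASON_KEYS))
  full <- c(MAM = 0, JJA = 0, SON = 0, DJF = 0)
  full[names(slopes)] <- slopes
  if (is.numeric(climatology) && is.null(dim(climatology))) {
    stopifnot(length(climatology) == 12L)
  } else stopifnot(length(dim(climatology)) == 3L, dim(climatology)[1] == 12L)
  if (any(climatology < 0, na.rm = TRUE))
    stop("climatology must be non-negative", call. = FALSE)
  structure(list(slopes = full, climatology = climatology,
                 noise_sd = noise_sd, pattern = pattern, seed = as.integer(seed)),
            class = "lai_scenario")
}

#' Default monthly LAI climatology (NH-typical seasonal cycle)
#' @return length-12 numeric vector (m2 m-2), peaking in July.
#' @export
default_lai_climatology <- function() {
  m <- 1:12
  0.35 + 1.4 * exp(-((m - 7) / 2.1)^2)
}

#' Generate a synthetic monthly LAI record
#'
#' Builds `LAI(y, m) = clim_m + slope_{season(m)} * (y - y0) / 10 *
#' pattern + noise`, clipped at zero, where `y0` is the first year of
#' the span. At zero noise the seasonal-mean trend recovered by
#' ordinary least squares equals the imposed slope exactly (for the
#' in-year seasons); the same seed always reproduces the same record.
#'
#' @param scenario an [lai_scenario()].
#' @param lat,lon grid axes.
#' @param years integer vector of consecutive calendar years (>= 2).
#' @return monthly [grid_field()] of LAI (m2 m-2) with an attribute
#'   `n_clipped` counting cells clipped at zero.
#' @export
generate_lai_scenario <- function(scenario, lat, lon, years) {
  stopifnot(inherits(scenario, "lai_scenario"), length(years) >= 2L)
  nlat <- length(lat); nlon <- length(lon); ny <- length(years)
  stamps <- month_stamps(years)
  nt <- nrow(stamps)
  pat <- if (is.null(scenario$pattern)) matrix(1, nlat, nlon) else scenario$pattern
  stopifnot(identical(dim(pat), c(nlat, nlon)))
  clim_slice <- function(m) {
    if (is.null(dim(scenario$climatology))) {
      matrix(scenario$climatology[m], nlat, nlon)
    } else scenario$climatology[m, , ]
  }
  y0 <- years[1]
  vals <- array(NA_real_, c(nt, nlat, nlon))
  noise <- if (scenario$noise_sd > 0) {
    with_seed(scenario$seed, array(stats::rnorm(nt * nlat * nlon, 0, scenario$noise_sd),
                                   c(nt, nlat, nlon)))
  } else array(0, c(nt, nlat, nlon))
  for (t in seq_len(nt)) {
    m <- stamps$month[t]
    slope <- scenario$slopes[[season_of_month(m)]]
    vals[t, , ] <- clim_slice(m) + slope * (stamps$year[t] - y0) / 10 * pat +
      noise[t, , ]
  }
  n_clipped <- sum(vals < 0)
  vals[vals < 0] <- 0
  out <- grid_field(vals, lat, lon, months = stamps, units = "m2 m-2", name = "lai")
  attr(out, "n_clipped") <- n_clipped
  out
}
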