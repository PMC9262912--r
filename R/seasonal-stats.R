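#' Ordinary least squares trend of a yearly series
#'
#' Fits `y ~ year` by OLS and reports the slope per decade, its
#' standard error (same scaling), the two-sided t-test p-value with
#' `n - 2` degrees of freedom, and the conventional significance class
#' (`***` p < 0.01, `**` p < 0.05, `*` p < 0.1, `n.s.` otherwise).
#' Residuals are assumed independent between years (no autocorrelation
#' correction).
#'
#' @param values yearly scalar series (length >= 3, NAs dropped
#'   pairwise with `years`).
#' @param years numeric time axis (calendar years).
#' @return object of class `trend_result`: list with `slope_decade`,
#'   `se_decade`, `p_value`, `stars`, `n`.
#' @export
ols_trend <- function(values, years) {
  ok <- !is.na(values) & !is.na(years)
  y <- values[ok]; x <- years[ok]
  n <- length(y)
  if (n < 3L) stop("trend estimation needs at least 3 points", call. = FALSE)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- sum(xc * y) / sxx
  resid <- y - mean(y) - slope * xc
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  if (se == 0) {
    p <- if (slope == 0) 1 else 0
  } else {
    p <- 2 * stats::pt(-abs(slope / se), df = n - 2)
  }
  structure(list(slope_decade = slope * 10, se_decade = se * 10,
                 p_value = p, stars = p_stars(p), n = n),
            class = "trend_result")
}

p_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "n.s.")))
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("trend %.4g +/- %.4g per decade (p = %.3g, %s; n = %d)\n",
              x$slope_decade, x$se_decade, x$p_value, x$stars, x$n))
  invisible(x)
}

#' Per-cell OLS trends over a yearly gridded series
#'
#' Vectorised least squares across the grid (algebraically identical
#' to fitting [ols_trend()] cell by cell): returns maps of the slope
#' per decade, its standard error and the two-sided p-value. Cells with
#' any missing year are masked.
#'
#' @param field an [annual_field()].
#' @return list of `[nlat x nlon]` matrices `slope_decade`,
#'   `se_decade`, `p_value`, plus `n`.
#' @export
trend_map <- function(field) {
  stopifnot(inherits(field, "annual_field"))
  d <- dim(field$values)
  n <- d[1]
  if (n < 3L) stop("trend estimation needs at least 3 years", call. = FALSE)
  y <- matrix(field$values, nrow = n)       # [years x cells]
  xc <- field$years - mean(field$years)
  sxx <- sum(xc^2)
  bad <- colSums(is.na(y)) > 0
  y[, bad] <- 0
  slope <- colSums(xc * y) / sxx
  fit <- outer(xc, slope) + matrix(colMeans(y), n, ncol(y), byrow = TRUE)
  s2 <- colSums((y - fit)^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tt <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[se == 0 & slope == 0] <- 1
  slope[bad] <- NA; se[bad] <- NA; p[bad] <- NA
  list(slope_decade = matrix(slope * 10, d[2], d[3]),
       se_decade = matrix(se * 10, d[2], d[3]),
       p_value = matrix(p, d[2], d[3]),
       n = n)
}

#' Seasonal amplitude of temperature (July minus January)
#'
#' For each calendar year with both months present, the amplitude is
#' July `T_a` minus January `T_a` of the same year. Gridded input
#' yields a per-cell [annual_field()]; a plain series (with its month
#' stamps) yields a numeric vector with a `years` attribute.
#'
#' @param ta monthly [grid_field()] of air temperature, or a numeric
#'   monthly series.
#' @param months `data.frame(year, month)` stamps, required for a
#'   plain-series input.
#' @return [annual_field()] or numeric per-year amplitude (K).
#' @export
sat_amplitude <- function(ta, months = NULL) {
  if (inherits(ta, "grid_field")) {
    stopifnot(is_time_field(ta))
    months <- ta$months
    vals <- ta$values
  } else {
    if (is.null(months)) stop("`months` stamps required for a series", call. = FALSE)
    months <- validate_months(months, length(ta), contiguous = FALSE)
    vals <- ta
  }
  jul <- months$year[months$month == 7L]
  jan <- months$year[months$month == 1L]
  years <- sort(intersect(jul, jan))
  if (length(years) == 0L) stop("no year has both July and January", call. = FALSE)
  pick <- function(y, m) which(months$year == y & months$month == m)
  if (inherits(ta, "grid_field")) {
    d <- dim(vals)
    out <- array(NA_real_, c(length(years), d[2], d[3]))
    for (i in seq_along(years))
      out[i, , ] <- vals[pick(years[i], 7L), , ] - vals[pick(years[i], 1L), , ]
    annual_field(out, ta$lat, ta$lon, years, units = ta$units,
                 name = "sat_amplitude")
  } else {
    amp <- vapply(years, function(y) vals[pick(y, 7L)] - vals[pick(y, 1L)],
                  numeric(1))
    attr(amp, "years") <- years
    amp
  }
}

#' Correlation between seasonal LAI and its induced temperature anomaly
#'
#' Pearson correlation of two yearly series, optionally after removing
#' a linear trend from each (so a shared trend cannot masquerade as
#' interannual covariation).
#'
#' @param lai_seasonal yearly LAI series.
#' @param delta_ta_seasonal yearly induced-temperature series, same
#'   length.
#' @param years time axis, required when `detrend = TRUE`.
#' @param detrend remove per-series linear trends first?
#' @return list with `r` and `p_value` (two-sided).
#' @export
lai_delta_correlation <- function(lai_seasonal, delta_ta_seasonal,
                                  years = seq_along(lai_seasonal),
                                  detrend = FALSE) {
  if (length(lai_seasonal) != length(delta_ta_seasonal))
    stop("series lengths differ", call. = FALSE)
  if (length(lai_seasonal) < 3L) stop("need at least 3 years", call. = FALSE)
  x <- lai_seasonal; y <- delta_ta_seasonal
  if (detrend) {
    x <- stats::residuals(stats::lm(x ~ years))
    y <- stats::residuals(stats::lm(y ~ years))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Binned phase-space summary of a response map
#'
#' Summarises a cellwise response (e.g. the trend of the induced
#' air-temperature change) in the plane spanned by two driver maps
#' (e.g. soil-moisture and geopotential-height trends): a 2-d binned
#' mean surface plus the two marginal partial-dependence curves (mean
#' response per bin of one driver, pooling over the other). Bins with
#' fewer than `min_count` cells are dropped.
#'
#' @param response `[nlat x nlon]` response map.
#' @param driver_x,driver_y `[nlat x nlon]` driver maps (x: e.g. soil
#'   moisture trend; y: e.g. z500 trend).
#' @param bins number of bins per axis (default 20).
#' @param min_count minimum cells per retained bin (default 5).
#' @param mask optional logical cell selector.
#' @return list with `surface` (bins x bins matrix of means),
#'   `x_centers`, `y_centers`, and data.frames `marginal_x`,
#'   `marginal_y` (`center`, `mean`, `se`, `n`).
#' @export
phase_space_summary <- function(response, driver_x, driver_y, bins = 20,
                                min_count = 5, mask = NULL) {
  stopifnot(identical(dim(response), dim(driver_x)),
            identical(dim(response), dim(driver_y)))
  keep <- !is.na(response) & !is.na(driver_x) & !is.na(driver_y)
  if (!is.null(mask)) keep <- keep & mask
  r <- response[keep]; x <- driver_x[keep]; y <- driver_y[keep]
  if (length(r) == 0L) stop("no usable cells", call. = FALSE)
  cut_axis <- function(v) {
    br <- seq(min(v), max(v), length.out = bins + 1L)
    br[1] <- br[1] - 1e-9; br[bins + 1L] <- br[bins + 1L] + 1e-9
    list(idx = findInterval(v, br, rightmost.closed = TRUE),
         centers = (br[-1] + br[-(bins + 1L)]) / 2)
  }
  cx <- cut_axis(x); cy <- cut_axis(y)
  surface <- matrix(NA_real_, bins, bins)
  for (i in seq_len(bins)) for (j in seq_len(bins)) {
    sel <- cx$idx == i & cy$idx == j
    if (sum(sel) >= min_count) surface[i, j] <- mean(r[sel])
  }
  marginal <- function(idx, centers) {
    df <- do.call(rbind, lapply(seq_len(bins), function(i) {
      sel <- idx == i
      n <- sum(sel)
      if (n < min_count) return(NULL)
      data.frame(center = centers[i], mean = mean(r[sel]),
                 se = stats::sd(r[sel]) / sqrt(n), n = n)
    }))
    df
  }
  list(surface = surface, x_centers = cx$centers, y_centers = cy$centers,
       marginal_x = marginal(cx$idx, cx$centers),
       marginal_y = marginal(cy$idx, cy$centers))
}

#' Latitudinal profile of a map
#'
#' Area-weighted mean of a cellwise map within consecutive latitude
#' bands, respecting the land mask.
#'
#' @param map `[nlat x nlon]` matrix.
#' @param lat cell-centre latitudes.
#' @param band_width_deg band width in degrees (default 10).
#' @param mask optional logical cell selector.
#' @return data.frame with `lat_lo`, `lat_hi`, `lat_mid`, `mean`, `n`.
#' @export
latitudinal_profile <- function(map, lat, band_width_deg = 10, mask = NULL) {
  stopifnot(dim(map)[1] == length(lat))
  lo0 <- floor(min(lat) / band_width_deg) * band_width_deg
  edges <- seq(lo0, max(lat) + band_width_deg, by = band_width_deg)
  out <- NULL
  for (k in seq_len(length(edges) - 1L)) {
    rows <- which(lat >= edges[k] & lat < edges[k + 1L])
    if (length(rows) == 0L) next
    sub <- map[rows, , drop = FALSE]
    msub <- if (is.null(mask)) NULL else mask[rows, , drop = FALSE]
    keep <- !is.na(sub) & (if (is.null(msub)) TRUE else msub)
    if (!any(keep)) next
    w <- matrix(cos(lat[rows] * pi / 180), length(rows), ncol(map))
    w[!keep] <- 0
    out <- rbind(out, data.frame(
      lat_lo = edges[k], lat_hi = edges[k + 1L],
      lat_mid = (edges[k] + edges[k + 1L]) / 2,
      mean = sum(sub * w, na.rm = TRUE) / sum(w),
      n = sum(keep)))
  }
  out
}

#' Significance stippling mask
#'
#' Marks cells whose per-cell trend is statistically significant at
#' level `alpha` (no multiple-testing correction), and reports the
#' significant fraction of land cells.
#'
#' @param p_map `[nlat x nlon]` matrix of two-sided p-values (e.g. from
#'   [trend_map()]).
#' @param alpha significance level (default 0.05).
#' @param mask optional logical land selector.
#' @return logical matrix (`TRUE` = stippled), with attribute
#'   `fraction` = significant share of (masked, non-missing) cells.
#' @export
stipple_mask <- function(p_map, alpha = 0.05, mask = NULL) {
  keep <- !is.na(p_map) & (if (is.null(mask)) TRUE else mask)
  sig <- keep & (p_map < alpha)
  out <- sig
  attr(out, "fraction") <- if (any(keep)) sum(sig) / sum(keep) else NA_real_
  out
}
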