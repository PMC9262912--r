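#' Gridded lat-lon(-time) field
#'
#' The universal data container shared by every stage of the pipeline: a
#' regular cell-centred latitude-longitude grid, optionally with a monthly
#' time axis, plus a units string. Masked (non-land, or below-threshold)
#' cells are stored as `NA` and are excluded from every reduction.
#'
#' @param values numeric matrix `[nlat x nlon]` for a static field, or a
#'   3-d array `[ntime x nlat x nlon]` for a monthly field.
#' @param lat numeric vector of cell-centre latitudes in degrees,
#'   strictly ascending, within \[-90, 90\].
#' @param lon numeric vector of cell-centre longitudes in degrees.
#' @param months for time fields, a `data.frame` with integer columns
#'   `year` and `month`; stamps must be unique and contiguous in calendar
#'   order. `NULL` for static fields.
#' @param units units string, preserved verbatim through I/O.
#' @param name optional variable name.
#' @param contiguous require month stamps to be contiguous in calendar
#'   order (the default); season-subset fields produced by
#'   [split_intra_inter()] relax this.
#'
#' @return An object of class `grid_field`.
#' @export
grid_field <- function(values, lat, lon, months = NULL, units = "", name = NULL,
                       contiguous = TRUE) {
  if (!is.numeric(values) && !is.logical(values))
    stop("`values` must be numeric", call. = FALSE)
  values <- if (is.logical(values)) array(as.double(values), dim(values)) else values
  if (is.null(dim(values))) stop("`values` must be a matrix or 3-d array", call. = FALSE)
  nd <- length(dim(values))
  if (!nd %in% c(2L, 3L)) stop("`values` must have 2 or 3 dimensions", call. = FALSE)
  if (any(lat < -90 | lat > 90)) stop("latitudes must lie in [-90, 90]", call. = FALSE)
  if (is.unsorted(lat, strictly = TRUE)) stop("latitudes must be strictly ascending", call. = FALSE)
  dlat <- if (nd == 2L) dim(values)[1] else dim(values)[2]
  dlon <- if (nd == 2L) dim(values)[2] else dim(values)[3]
  if (dlat != length(lat) || dlon != length(lon))
    stop("value dimensions do not match lat/lon axes", call. = FALSE)
  if (nd == 3L) {
    if (is.null(months)) stop("time-typed field requires `months` stamps", call. = FALSE)
    months <- validate_months(months, dim(values)[1], contiguous = contiguous)
  } else if (!is.null(months)) {
    stop("static field must not carry `months`", call. = FALSE)
  }
  structure(
    list(values = values, lat = as.double(lat), lon = as.double(lon),
         months = months, units = units, name = name),
    class = "grid_field"
  )
}

validate_months <- function(months, ntime, contiguous = TRUE, unique = TRUE) {
  months <- as.data.frame(months)
  if (!all(c("year", "month") %in% names(months)))
    stop("`months` must have columns year and month", call. = FALSE)
  if (nrow(months) != ntime)
    stop("number of month stamps does not match the time dimension", call. = FALSE)
  if (any(months$month < 1 | months$month > 12))
    stop("month stamps must lie in 1..12", call. = FALSE)
  idx <- months$year * 12L + (months$month - 1L)
  if (unique && anyDuplicated(idx)) stop("month stamps must be unique", call. = FALSE)
  if (contiguous && ntime > 1L && !all(diff(idx) == 1L))
    stop("month stamps must be contiguous in calendar order", call. = FALSE)
  data.frame(year = as.integer(months$year), month = as.integer(months$month))
}

#' @export
print.grid_field <- function(x, ...) {
  d <- dim(x$values)
  if (is_time_field(x)) {
    cat(sprintf("<grid_field%s> %d months x %d lat x %d lon [%s]\n",
                if (is.null(x$name)) "" else paste0(" ", x$name),
                d[1], d[2], d[3], x$units))
    cat(sprintf("  span %d-%02d .. %d-%02d, %d masked cell-months\n",
                x$months$year[1], x$months$month[1],
                x$months$year[d[1]], x$months$month[d[1]],
                sum(is.na(x$values))))
  } else {
    cat(sprintf("<grid_field%s> %d lat x %d lon [%s], %d masked cells\n",
                if (is.null(x$name)) "" else paste0(" ", x$name),
                d[1], d[2], x$units, sum(is.na(x$values))))
  }
  invisible(x)
}

#' Does a field carry a time axis?
#' @param field a `grid_field`.
#' @return `TRUE` for a `[time x lat x lon]` field.
#' @export
is_time_field <- function(field) {
  stopifnot(inherits(field, "grid_field") || inherits(field, "annual_field"))
  length(dim(field$values)) == 3L
}

#' Annual (one value per year) gridded series
#'
#' Companion container to [grid_field()] for per-year aggregates such as
#' seasonal means: the time axis is indexed by `years` rather than by
#' monthly stamps.
#'
#' @param values array `[nyear x nlat x nlon]`.
#' @param lat,lon grid axes as in [grid_field()].
#' @param years integer vector of labelling years, strictly increasing.
#' @param units units string.
#' @param season optional season label ("MAM", "JJA", "SON", "DJF").
#' @param name optional variable name.
#' @return An object of class `annual_field`.
#' @export
annual_field <- function(values, lat, lon, years, units = "", season = NULL,
                         name = NULL) {
  if (length(dim(values)) != 3L) stop("`values` must be [year x lat x lon]", call. = FALSE)
  if (dim(values)[1] != length(years)) stop("years do not match time axis", call. = FALSE)
  if (length(years) > 1L && is.unsorted(years, strictly = TRUE))
    stop("`years` must be strictly increasing", call. = FALSE)
  structure(
    list(values = values, lat = as.double(lat), lon = as.double(lon),
         years = as.integer(years), units = units, season = season, name = name),
    class = "annual_field"
  )
}

#' @export
print.annual_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<annual_field%s%s> %d years (%d..%d) x %d lat x %d lon [%s]\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              if (is.null(x$season)) "" else paste0(" ", x$season),
              d[1], x$years[1], x$years[d[1]], d[2], d[3], x$units))
  invisible(x)
}

# ---- seasons -----------------------------------------------------------

SEASON_KEYS <- c("MAM", "JJA", "SON", "DJF")
SEASON_MONTHS <- list(MAM = c(3L, 4L, 5L), JJA = c(6L, 7L, 8L),
                      SON = c(9L, 10L, 11L), DJF = c(12L, 1L, 2L))

#' Meteorological season containing a calendar month
#'
#' Months partition into the standard meteorological seasons
#' March-April-May (MAM), June-July-August (JJA),
#' September-October-November (SON) and December-January-February (DJF).
#'
#' @param month integer month(s) in 1..12.
#' @return character vector of season keys, one per input month.
#' @export
season_of_month <- function(month) {
  if (any(is.na(month)) || any(month != as.integer(month)) ||
      any(month < 1) || any(month > 12))
    stop("`month` must be an integer in 1..12", call. = FALSE)
  key <- character(length(month))
  for (s in SEASON_KEYS) key[month %in% SEASON_MONTHS[[s]]] <- s
  key
}

#' Member months of a season
#' @param season one of "MAM", "JJA", "SON", "DJF".
#' @return integer vector of three calendar months.
#' @export
season_months <- function(season) {
  season <- match.arg(season, SEASON_KEYS)
  SEASON_MONTHS[[season]]
}

#' Per-year seasonal mean of a monthly field
#'
#' Averages the three member months of a season within each year.
#' DJF spans the calendar-year boundary: the DJF labelled with year `y`
#' aggregates December of `y` with January and February of `y + 1`
#' (the winter that follows growing-season year `y`), so a record of
#' `n` calendar years yields `n - 1` DJF values; a trailing incomplete
#' DJF is dropped. For the in-year seasons, years missing any member
#' month are dropped.
#'
#' @param field a monthly `grid_field`.
#' @param season season key.
#' @return An [annual_field()] of per-year seasonal means.
#' @export
seasonal_series <- function(field, season) {
  stopifnot(inherits(field, "grid_field"), is_time_field(field))
  season <- match.arg(season, SEASON_KEYS)
  mm <- season_months(season)
  st <- field$months
  # label each stamp with the season-year it belongs to
  if (season == "DJF") {
    in_season <- st$month %in% mm
    year_lab <- ifelse(st$month == 12L, st$year, st$year - 1L)
  } else {
    in_season <- st$month %in% mm
    year_lab <- st$year
  }
  sel <- which(in_season)
  if (length(sel) == 0L)
    stop(sprintf("no %s months present in field", season), call. = FALSE)
  labs <- year_lab[sel]
  keep_years <- as.integer(names(which(table(labs) == 3L)))
  keep_years <- sort(keep_years)
  if (length(keep_years) == 0L)
    stop(sprintf("no complete %s season in field", season), call. = FALSE)
  d <- dim(field$values)
  out <- array(NA_real_, c(length(keep_years), d[2], d[3]))
  for (i in seq_along(keep_years)) {
    rows <- sel[labs == keep_years[i]]
    out[i, , ] <- apply(field$values[rows, , , drop = FALSE], c(2, 3), mean)
  }
  annual_field(out, field$lat, field$lon, keep_years, units = field$units,
               season = season, name = field$name)
}

# ---- masking and area weighting ---------------------------------------

#' Land mask from climatological LAI
#'
#' A cell is retained iff its time-mean LAI meets the threshold
#' (default 0.1 m2 m-2, boundary inclusive); cells that are masked at
#' every time step are dropped.
#'
#' @param lai monthly LAI `grid_field` over the full record.
#' @param threshold minimum climatological LAI (m2 m-2).
#' @return logical `[nlat x nlon]` matrix, `TRUE` for retained cells,
#'   with a `derivation` attribute recording the rule.
#' @export
climatological_lai_mask <- function(lai, threshold = 0.1) {
  stopifnot(inherits(lai, "grid_field"), is_time_field(lai))
  clim <- apply(lai$values, c(2, 3), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  mask <- !is.na(clim) & clim >= threshold
  attr(mask, "derivation") <- sprintf("climatological LAI >= %g", threshold)
  mask
}

#' Cosine-latitude area-weighted mean over a mask
#'
#' Weights are proportional to `cos(lat)` of each retained cell and are
#' renormalised over the cells that are both unmasked and non-missing at
#' each time step, so a constant field is a fixed point of the reduction.
#'
#' @param field a `grid_field`, `annual_field`, or plain `[nlat x nlon]`
#'   matrix.
#' @param mask optional logical `[nlat x nlon]` mask (`TRUE` = keep);
#'   `NULL` keeps all cells.
#' @param lat latitudes, required only when `field` is a bare matrix.
#' @return scalar for static input, otherwise one value per time step.
#' @export
area_weighted_mean <- function(field, mask = NULL, lat = NULL) {
  if (inherits(field, "grid_field") || inherits(field, "annual_field")) {
    lat <- field$lat
    vals <- field$values
  } else {
    if (is.null(lat)) stop("`lat` required for bare-matrix input", call. = FALSE)
    vals <- field
  }
  nd <- length(dim(vals))
  nlat <- if (nd == 2L) dim(vals)[1] else dim(vals)[2]
  nlon <- if (nd == 2L) dim(vals)[2] else dim(vals)[3]
  w <- matrix(cos(lat * pi / 180), nlat, nlon)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(w)))
    w[!mask] <- 0
  }
  wmean <- function(slice) {
    ww <- w
    ww[is.na(slice)] <- 0
    tot <- sum(ww)
    if (tot <= 0) stop("all cells masked in area_weighted_mean", call. = FALSE)
    sum(slice * ww, na.rm = TRUE) / tot
  }
  if (nd == 2L) return(wmean(vals))
  vapply(seq_len(dim(vals)[1]), function(t) wmean(vals[t, , ]), numeric(1))
}

#' Monthly climatology of a monthly field
#'
#' @param field monthly `grid_field`.
#' @return array `[12 x nlat x nlon]` of per-calendar-month means over
#'   all years present.
#' @export
monthly_climatology <- function(field) {
  stopifnot(inherits(field, "grid_field"), is_time_field(field))
  d <- dim(field$values)
  out <- array(NA_real_, c(12L, d[2], d[3]))
  for (m in 1:12) {
    rows <- which(field$months$month == m)
    if (length(rows) > 0L)
      out[m, , ] <- apply(field$values[rows, , , drop = FALSE], c(2, 3), mean)
  }
  out
}

#' Month stamps for a span of calendar years
#' @param years integer vector of consecutive years.
#' @return `data.frame(year, month)` covering January..December of each year.
#' @export
month_stamps <- function(years) {
  data.frame(year = rep(as.integer(years), each = 12L), month = rep(1:12, length(years)))
}
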