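#' Monthly maximum of sub-monthly LAI composites
#'
#' Satellite LAI is distributed as ~15-day composites; the monthly maps
#' used to force the experiments take, per cell, the maximum over all
#' composites stamped within each calendar month. The operation is
#' idempotent and invariant to the order of composites within a month.
#'
#' @param values array `[ncomposite x nlat x nlon]` of composite LAI.
#' @param stamps `data.frame(year, month)` with one row per composite;
#'   several composites may share a month.
#' @param lat,lon grid axes.
#' @param units units string for the output field.
#' @return monthly [grid_field()] of per-month maxima.
#' @export
monthly_max_composite <- function(values, stamps, lat, lon, units = "m2 m-2") {
  stopifnot(length(dim(values)) == 3L)
  stamps <- validate_months(stamps, dim(values)[1], contiguous = FALSE,
                            unique = FALSE)
  idx <- stamps$year * 12L + (stamps$month - 1L)
  uidx <- sort(unique(idx))
  if (length(uidx) > 1L && !all(diff(uidx) == 1L)) {
    gaps <- setdiff(seq(uidx[1], uidx[length(uidx)]), uidx)
    stop(sprintf("months with zero composites: %s",
                 paste(sprintf("%d-%02d", gaps %/% 12L, gaps %% 12L + 1L),
                       collapse = ", ")), call. = FALSE)
  }
  d <- dim(values)
  out <- array(NA_real_, c(length(uidx), d[2], d[3]))
  for (i in seq_along(uidx)) {
    rows <- which(idx == uidx[i])
    out[i, , ] <- apply(values[rows, , , drop = FALSE], c(2, 3), function(v) {
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    })
  }
  grid_field(out, lat, lon,
             months = data.frame(year = uidx %/% 12L, month = uidx %% 12L + 1L),
             units = units, name = "lai")
}

#' Aggregate a fine grid to an integrally nesting coarse grid
#'
#' Each coarse cell is the cosine-latitude area-weighted mean of its
#' unmasked fine children; a coarse cell whose children are all masked is
#' itself masked. The fine grid must nest integrally (an integer number
#' of fine cells per coarse cell along each axis).
#'
#' @param fine a static or monthly [grid_field()].
#' @param factor_lat,factor_lon integer nesting factors.
#' @return a [grid_field()] on the coarse grid.
#' @export
aggregate_to_grid <- function(fine, factor_lat, factor_lon = factor_lat) {
  stopifnot(inherits(fine, "grid_field"))
  nlat <- length(fine$lat); nlon <- length(fine$lon)
  if (factor_lat < 1 || factor_lon < 1 ||
      nlat %% factor_lat != 0L || nlon %% factor_lon != 0L)
    stop("fine grid does not nest integrally in the coarse grid", call. = FALSE)
  clat_n <- nlat %/% factor_lat; clon_n <- nlon %/% factor_lon
  glat <- rep(seq_len(clat_n), each = factor_lat)
  glon <- rep(seq_len(clon_n), each = factor_lon)
  coarse_lat <- as.vector(tapply(fine$lat, glat, mean))
  coarse_lon <- as.vector(tapply(fine$lon, glon, mean))
  w <- matrix(cos(fine$lat * pi / 180), nlat, nlon)
  agg_slice <- function(slice) {
    out <- matrix(NA_real_, clat_n, clon_n)
    for (i in seq_len(clat_n)) {
      ri <- which(glat == i)
      for (j in seq_len(clon_n)) {
        cj <- which(glon == j)
        v <- slice[ri, cj]; ww <- w[ri, cj]
        ww[is.na(v)] <- 0
        if (sum(ww) > 0) out[i, j] <- sum(v * ww, na.rm = TRUE) / sum(ww)
      }
    }
    out
  }
  if (is_time_field(fine)) {
    d <- dim(fine$values)
    out <- array(NA_real_, c(d[1], clat_n, clon_n))
    for (t in seq_len(d[1])) out[t, , ] <- agg_slice(fine$values[t, , ])
    grid_field(out, coarse_lat, coarse_lon, months = fine$months,
               units = fine$units, name = fine$name)
  } else {
    grid_field(agg_slice(fine$values), coarse_lat, coarse_lon,
               units = fine$units, name = fine$name)
  }
}

#' Distribute cell LAI to plant functional types
#'
#' Every vegetated plant functional type (PFT) present in a cell is
#' assigned the cell's satellite LAI; the bare-soil class receives 0.
#' With this convention the cover-weighted mean over vegetated classes
#' reconstructs the cell LAI exactly, conserving the satellite value
#' that the experiments prescribe.
#'
#' @param cell_lai static or monthly [grid_field()] of cell-mean LAI.
#' @param cover array `[npft x nlat x nlon]` of fractional cover per
#'   class; fractions are non-negative and sum to at most 1 (+1e-6).
#' @param bare_index index (or indices) of the bare-soil class within
#'   the first axis of `cover`.
#' @return list with `pft_lai` (array `[npft x ...]` matching
#'   `cell_lai`'s shape per class) and `reconstructed` (cover-weighted
#'   vegetated mean, same shape as `cell_lai$values`). Cells with zero
#'   vegetated fraction but non-zero LAI are masked with a warning.
#' @export
pft_level_lai <- function(cell_lai, cover, bare_index = dim(cover)[1]) {
  stopifnot(inherits(cell_lai, "grid_field"), length(dim(cover)) == 3L)
  npft <- dim(cover)[1]
  if (any(cover < 0, na.rm = TRUE))
    stop("cover fractions must be non-negative", call. = FALSE)
  tot <- apply(cover, c(2, 3), sum)
  if (any(tot > 1 + 1e-6, na.rm = TRUE))
    stop("cover fractions sum to more than 1", call. = FALSE)
  dgrid <- dim(cover)[2:3]
  veg_idx <- setdiff(seq_len(npft), bare_index)
  cover_k <- function(k) matrix(cover[k, , ], dgrid[1], dgrid[2])
  fveg <- Reduce(`+`, lapply(veg_idx, cover_k))
  static <- !is_time_field(cell_lai)
  lai_rep <- cell_lai$values
  peak <- if (static) lai_rep else
    matrix(apply(lai_rep, c(2, 3), max, na.rm = TRUE), dgrid[1], dgrid[2])
  bad <- (fveg <= 0) & !is.na(peak) & (peak > 0)
  if (any(bad, na.rm = TRUE)) {
    warning(sprintf("%d cell(s) with zero vegetated fraction but non-zero LAI; masked",
                    sum(bad, na.rm = TRUE)), call. = FALSE)
  }
  assign_class <- function(k) {
    has <- (cover_k(k) > 0) & !(k %in% bare_index)
    mask_slice <- function(sl) {
      out <- matrix(ifelse(has, sl, 0), dgrid[1], dgrid[2])
      out[bad] <- NA_real_
      out
    }
    if (static) {
      mask_slice(lai_rep)
    } else {
      d <- dim(lai_rep)
      out <- array(0, d)
      for (t in seq_len(d[1])) out[t, , ] <- mask_slice(lai_rep[t, , ])
      out
    }
  }
  pft_lai <- lapply(seq_len(npft), assign_class)
  # cover-weighted vegetated mean reconstructs the cell value
  recon_slice <- function(sl) {
    sl <- matrix(sl, dgrid[1], dgrid[2])
    num <- matrix(0, dgrid[1], dgrid[2])
    for (k in veg_idx) {
      ck <- cover_k(k)
      num <- num + ck * ifelse(ck > 0, sl, 0)
    }
    out <- matrix(ifelse(fveg > 0, num / fveg, 0), dgrid[1], dgrid[2])
    out[bad] <- NA_real_
    out
  }
  reconstructed <- if (static) recon_slice(lai_rep) else {
    d <- dim(lai_rep)
    arr <- array(NA_real_, d)
    for (t in seq_len(d[1])) arr[t, , ] <- recon_slice(lai_rep[t, , ])
    arr
  }
  list(pft_lai = pft_lai, reconstructed = reconstructed, veg_fraction = fveg)
}
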