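#' Write a gridded field to a portable text file
#'
#' Fields are stored in a self-describing JSON dialect with named axes
#' (`lat`, `lon`, and `months` for time fields), a verbatim `units`
#' attribute, and values serialised at full double precision; masked
#' cells are stored as `null`. The round trip through [read_field()]
#' preserves values bit-for-bit within float64, coordinates, stamps,
#' units and mask.
#'
#' @param field a [grid_field()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "grid_field"))
  doc <- list(
    format = "greenfeedback-grid-1",
    name = field$name,
    units = field$units,
    lat = field$lat,
    lon = field$lon,
    dims = if (is_time_field(field)) c("time", "lat", "lon") else c("lat", "lon"),
    shape = dim(field$values),
    values = as.vector(field$values)  # column-major order
  )
  if (is_time_field(field)) {
    doc$months <- list(year = field$months$year, month = field$months$month)
  }
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", na = "null", pretty = FALSE)
  invisible(path)
}

#' Read a gridded field written by [write_field()]
#'
#' @param path input file path.
#' @param expect_time if `TRUE`, fail unless the file carries a time axis.
#' @return a [grid_field()].
#' @export
read_field <- function(path, expect_time = FALSE) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format) || !identical(doc$format, "greenfeedback-grid-1"))
    stop("not a recognised gridded-field file: ", path, call. = FALSE)
  for (ax in c("lat", "lon", "shape", "values"))
    if (is.null(doc[[ax]]))
      stop(sprintf("malformed field file: missing axis/attribute '%s'", ax), call. = FALSE)
  shape <- as.integer(doc$shape)
  vals <- array(as.double(doc$values), dim = shape)
  has_time <- length(shape) == 3L
  if (expect_time && !has_time)
    stop("field file has no 'time' axis but a time-typed field was requested",
         call. = FALSE)
  months <- NULL
  if (has_time) {
    if (is.null(doc$months))
      stop("malformed field file: time axis without 'months' stamps", call. = FALSE)
    months <- data.frame(year = as.integer(doc$months$year),
                         month = as.integer(doc$months$month))
  }
  grid_field(vals, lat = as.double(doc$lat), lon = as.double(doc$lon),
             months = months, units = if (is.null(doc$units)) "" else doc$units,
             name = doc$name)
}
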