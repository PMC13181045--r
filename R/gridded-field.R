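#' Construct a GriddedField
#'
#' @param dates `Date` vector, strictly increasing (daily product slices).
#' @param depths vertical levels in metres, strictly increasing.
#' @param lats,lons cell-centre coordinates, decimal degrees, increasing.
#' @param values numeric array `[time, depth, lat, lon]`, degrees Celsius.
#' @param mask optional logical `[lat, lon]` sea mask; default all sea.
#' @return a [GriddedField-class] object.
#' @export
griddedField <- function(dates, depths, lats, lons, values, mask = NULL) {
  if (is.null(mask))
    mask <- matrix(TRUE, nrow = length(lats), ncol = length(lons))
  obj <- new("GriddedField",
             dates = as.Date(dates), depths = as.numeric(depths),
             lats = as.numeric(lats), lons = as.numeric(lons),
             values = values, mask = mask)
  validObject(obj)
  obj
}

#' Read / write a gridded field as plain text
#'
#' Long-format CSV serialization of a [GriddedField-class]: one row per
#' `(date, depth_m, lat, lon)` grid node with the temperature in `temp_c`
#' (blank over land). Axes are recovered from the unique coordinate values;
#' a grid node whose temperature is blank at every date and depth is treated
#' as a land cell.
#'
#' @param field a `GriddedField`.
#' @param path file path.
#' @return `writeGriddedField` returns `path` invisibly; `readGriddedField`
#'   returns a `GriddedField`.
#' @export
writeGriddedField <- function(field, path) {
  g <- expand.grid(date = fieldDates(field), depth_m = fieldDepths(field),
                   lat = fieldLats(field), lon = fieldLons(field),
                   KEEP.OUT.ATTRS = FALSE)
  g$temp_c <- as.vector(fieldValues(field))
  data.table::fwrite(g, path, na = "")
  invisible(path)
}

#' @rdname writeGriddedField
#' @export
readGriddedField <- function(path) {
  if (!file.exists(path)) stop("field file not found: ", path, call. = FALSE)
  d <- data.table::fread(path, colClasses = list(
    character = "date", numeric = c("depth_m", "lat", "lon", "temp_c")))
  dates <- sort(unique(as.Date(d$date)))
  depths <- sort(unique(d$depth_m))
  lats <- sort(unique(d$lat))
  lons <- sort(unique(d$lon))
  dims <- c(length(dates), length(depths), length(lats), length(lons))
  if (nrow(d) != prod(dims))
    stop("field file is not a complete grid", call. = FALSE)
  idx <- cbind(match(as.Date(d$date), dates), match(d$depth_m, depths),
               match(d$lat, lats), match(d$lon, lons))
  values <- array(NA_real_, dim = dims)
  values[idx] <- d$temp_c
  wet <- apply(!is.na(values), c(3, 4), any)
  griddedField(dates, depths, lats, lons, values, mask = wet)
}
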