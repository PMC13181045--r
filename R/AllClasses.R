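#' @import methods
#' @importFrom S4Vectors SimpleList
NULL

#' Gridded 4-D seawater temperature field
#'
#' In-memory container for a daily gridded temperature product (the "model
#' product" a set of reconstructed profiles is validated against). The value
#' array is organised as `[time, depth, lat, lon]`, in degrees Celsius, with a
#' logical sea mask over the horizontal grid (`TRUE` = sea, `FALSE` = land).
#'
#' @slot dates daily time axis, class `Date`, strictly increasing.
#' @slot depths vertical levels in metres, strictly increasing.
#' @slot lats,lons cell-centre coordinates in decimal degrees, strictly
#'   increasing, regular spacing.
#' @slot values numeric array `[time, depth, lat, lon]` of temperatures (degC);
#'   `NA` over land cells.
#' @slot mask logical `[lat, lon]` matrix; `TRUE` where the water column exists.
#'
#' @seealso [griddedField()], [generateModelField()], [readGriddedField()]
#' @export
setClass("GriddedField",
  representation(
    dates  = "Date",
    depths = "numeric",
    lats   = "numeric",
    lons   = "numeric",
    values = "array",
    mask   = "matrix"
  )
)

setValidity("GriddedField", function(object) {
  msg <- character()
  chkInc <- function(x, nm) {
    if (length(x) < 1L) return(sprintf("'%s' axis is empty", nm))
    if (anyNA(x)) return(sprintf("'%s' axis contains NA", nm))
    if (length(x) > 1L && any(diff(as.numeric(x)) <= 0))
      return(sprintf("'%s' axis is not strictly increasing", nm))
    NULL
  }
  for (nm in c("dates", "depths", "lats", "lons")) {
    m <- chkInc(slot(object, nm), nm)
    if (!is.null(m)) msg <- c(msg, m)
  }
  dims <- c(length(object@dates), length(object@depths),
            length(object@lats), length(object@lons))
  if (!identical(dim(object@values), as.integer(dims)))
    msg <- c(msg, "dim(values) does not match the axis lengths")
  if (!is.logical(object@mask) ||
      !identical(dim(object@mask), as.integer(dims[3:4])))
    msg <- c(msg, "mask must be a logical [lat, lon] matrix")
  if (length(msg)) msg else TRUE
})

#' A reconstructed dive temperature profile
#'
#' One dive's chronological sequence of (timestamp, depth, temperature)
#' samples together with the governing satellite fix (position, UTC time,
#' Argos location quality class).
#'
#' @slot tagId tag identifier.
#' @slot diveId dive identifier, unique within a tag.
#' @slot fixUtc `POSIXct` (UTC) time of the satellite fix the dive was
#'   transmitted under.
#' @slot lat,lon fix position in decimal degrees.
#' @slot lq Argos location quality class (one of Z, B, A, 0, 1, 2, 3).
#' @slot samples `data.frame` with columns `utc` (`POSIXct`), `depth_m`,
#'   `temp_c`; timestamps strictly increasing on the tag's sampling lattice,
#'   depths strictly positive.
#'
#' @seealso [decodeTagFile()], [diveSamples()]
#' @export
setClass("DiveProfile",
  representation(
    tagId   = "character",
    diveId  = "character",
    fixUtc  = "POSIXct",
    lat     = "numeric",
    lon     = "numeric",
    lq      = "character",
    samples = "data.frame"
  )
)

setValidity("DiveProfile", function(object) {
  msg <- character()
  s <- object@samples
  need <- c("utc", "depth_m", "temp_c")
  if (!all(need %in% names(s)))
    return("samples must have columns utc, depth_m, temp_c")
  if (nrow(s)) {
    if (anyNA(s$utc) || anyNA(s$depth_m))
      msg <- c(msg, "samples contain NA time or depth")
    tt <- as.numeric(s$utc)
    if (nrow(s) > 1L && any(diff(tt) <= 0))
      msg <- c(msg, "sample timestamps are not strictly increasing")
    if (any(s$depth_m <= 0, na.rm = TRUE))
      msg <- c(msg, "sample depths must be strictly positive")
  }
  if (length(object@lq) != 1L) msg <- c(msg, "lq must be length 1")
  if (length(msg)) msg else TRUE
})

#' List of dive profiles
#'
#' A [S4Vectors::SimpleList] whose elements are [DiveProfile-class] objects.
#' @export
setClass("DiveProfileList",
  contains = "SimpleList",
  prototype = prototype(elementType = "DiveProfile")
)

#' Named sub-region polygons
#'
#' A prioritised set of named polygons (lon/lat vertex matrices) used to
#' stratify matched pairs spatially. Polygons are tested in order; the first
#' polygon containing a point wins, points outside all polygons are labelled
#' `"other"`.
#'
#' @slot names region names, in priority order.
#' @slot polygons list of two-column numeric matrices (lon, lat), one per
#'   region, same order as `names`.
#'
#' @seealso [readRegionSet()], [assignSubregion()]
#' @export
setClass("RegionSet",
  representation(names = "character", polygons = "list")
)

setValidity("RegionSet", function(object) {
  msg <- character()
  if (length(object@names) != length(object@polygons))
    msg <- c(msg, "names and polygons differ in length")
  if (anyDuplicated(object@names))
    msg <- c(msg, "region names must be unique")
  for (i in seq_along(object@polygons)) {
    p <- object@polygons[[i]]
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L || anyNA(p))
      msg <- c(msg, sprintf("polygon '%s' is not a valid vertex matrix",
                            object@names[i]))
  }
  if (length(msg)) msg else TRUE
})
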