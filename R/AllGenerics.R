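#' @include AllClasses.R
NULL

#' Accessors for GriddedField and DiveProfile objects
#'
#' Standard read-only accessors: `fieldDates()`, `fieldDepths()`,
#' `fieldLats()`, `fieldLons()`, `fieldValues()`, `seaMask()` for
#' [GriddedField-class]; `tagId()`, `diveId()`, `fixTime()`, `fixLon()`,
#' `fixLat()`, `locationQuality()`, `diveSamples()` for [DiveProfile-class].
#'
#' @param x a `GriddedField` or `DiveProfile` object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases fieldDates fieldDepths fieldLats fieldLons fieldValues seaMask
#'   tagId diveId fixTime fixLon fixLat locationQuality diveSamples
NULL

#' @rdname accessors
#' @export
setGeneric("fieldDates", function(x) standardGeneric("fieldDates"))
#' @rdname accessors
#' @export
setGeneric("fieldDepths", function(x) standardGeneric("fieldDepths"))
#' @rdname accessors
#' @export
setGeneric("fieldLats", function(x) standardGeneric("fieldLats"))
#' @rdname accessors
#' @export
setGeneric("fieldLons", function(x) standardGeneric("fieldLons"))
#' @rdname accessors
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))
#' @rdname accessors
#' @export
setGeneric("seaMask", function(x) standardGeneric("seaMask"))
#' @rdname accessors
#' @export
setGeneric("tagId", function(x) standardGeneric("tagId"))
#' @rdname accessors
#' @export
setGeneric("diveId", function(x) standardGeneric("diveId"))
#' @rdname accessors
#' @export
setGeneric("fixTime", function(x) standardGeneric("fixTime"))
#' @rdname accessors
#' @export
setGeneric("fixLon", function(x) standardGeneric("fixLon"))
#' @rdname accessors
#' @export
setGeneric("fixLat", function(x) standardGeneric("fixLat"))
#' @rdname accessors
#' @export
setGeneric("locationQuality", function(x) standardGeneric("locationQuality"))
#' @rdname accessors
#' @export
setGeneric("diveSamples", function(x) standardGeneric("diveSamples"))

#' @rdname accessors
setMethod("fieldDates",  "GriddedField", function(x) x@dates)
#' @rdname accessors
setMethod("fieldDepths", "GriddedField", function(x) x@depths)
#' @rdname accessors
setMethod("fieldLats",   "GriddedField", function(x) x@lats)
#' @rdname accessors
setMethod("fieldLons",   "GriddedField", function(x) x@lons)
#' @rdname accessors
setMethod("fieldValues", "GriddedField", function(x) x@values)
#' @rdname accessors
setMethod("seaMask",     "GriddedField", function(x) x@mask)
#' @rdname accessors
setMethod("tagId",  "DiveProfile", function(x) x@tagId)
#' @rdname accessors
setMethod("diveId", "DiveProfile", function(x) x@diveId)
#' @rdname accessors
setMethod("fixTime", "DiveProfile", function(x) x@fixUtc)
#' @rdname accessors
setMethod("fixLon", "DiveProfile", function(x) x@lon)
#' @rdname accessors
setMethod("fixLat", "DiveProfile", function(x) x@lat)
#' @rdname accessors
setMethod("locationQuality", "DiveProfile", function(x) x@lq)
#' @rdname accessors
setMethod("diveSamples", "DiveProfile", function(x) x@samples)

setMethod("show", "GriddedField", function(object) {
  cat(sprintf("GriddedField: %d dates x %d depths x %d lat x %d lon\n",
              length(object@dates), length(object@depths),
              length(object@lats), length(object@lons)))
  cat(sprintf("  dates : %s .. %s\n", min(object@dates), max(object@dates)))
  cat(sprintf("  depth : %.2f .. %.2f m (%d levels)\n",
              min(object@depths), max(object@depths), length(object@depths)))
  cat(sprintf("  lat   : %.4f .. %.4f deg\n", min(object@lats), max(object@lats)))
  cat(sprintf("  lon   : %.4f .. %.4f deg\n", min(object@lons), max(object@lons)))
  cat(sprintf("  sea cells: %d of %d\n", sum(object@mask), length(object@mask)))
  invisible(NULL)
})

setMethod("show", "DiveProfile", function(object) {
  s <- object@samples
  cat(sprintf("DiveProfile %s/%s  fix %s UTC  LQ %s  (%.4fN, %.4fE)\n",
              object@tagId, object@diveId,
              format(object@fixUtc, "%Y-%m-%d %H:%M"),
              object@lq, object@lat, object@lon))
  if (nrow(s)) {
    cat(sprintf("  %d samples, %s .. %s, depth %.1f-%.1f m\n",
                nrow(s), format(min(s$utc), "%H:%M"),
                format(max(s$utc), "%H:%M"),
                min(s$depth_m), max(s$depth_m)))
  } else {
    cat("  0 samples\n")
  }
  invisible(NULL)
})

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet with %d regions (priority order): %s\n",
              length(object@names), paste(object@names, collapse = " > ")))
  invisible(NULL)
})
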