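## Internal helpers shared across modules.

#' Great-circle distance in kilometres
#'
#' Haversine distance between points given in decimal degrees.
#'
#' @param lon1,lat1 coordinates of the first point(s).
#' @param lon2,lat2 coordinates of the second point(s).
#' @return distance(s) in kilometres.
#' @export
haversineKm <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

## Parse ISO-8601 UTC timestamps; returns POSIXct (tz UTC), NA where blank.
parseUtc <- function(x) {
  x <- trimws(x)
  out <- rep(as.POSIXct(NA), length(x))
  nz <- !is.na(x) & nzchar(x)
  if (any(nz)) {
    v <- as.POSIXct(x[nz], format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    v2 <- as.POSIXct(x[nz], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
    v[is.na(v)] <- v2[is.na(v)]
    out[nz] <- v
  }
  attr(out, "tzone") <- "UTC"
  out
}

formatUtc <- function(x) {
  ifelse(is.na(x), "", format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
}

## Full-precision numeric formatting so encode -> decode round trips exactly.
numToChar <- function(x) {
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

## as.numeric with blank -> NA and a parse error naming the offending line.
numFromChar <- function(x, lines, field) {
  x <- trimws(x)
  blank <- is.na(x) | !nzchar(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- !blank & is.na(out)
  if (any(bad)) {
    stop(sprintf("parse error at line %d: field '%s' is not numeric ('%s')",
                 lines[which(bad)[1]], field, x[which(bad)[1]]), call. = FALSE)
  }
  out
}

## Deterministic sub-seed derivation, kept well inside 32-bit integer range.
deriveSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
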