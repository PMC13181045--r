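#' Assign a meteorological season to a date
#'
#' DJF = winter, MAM = spring, JJA = summer, SON = autumn.
#'
#' @param date `Date` (or coercible) vector.
#' @return character vector in `c("winter", "spring", "summer", "autumn")`.
#' @export
assignSeason <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "autumn", "autumn", "autumn", "winter")[m]
}

seasonLevels <- function() c("winter", "spring", "summer", "autumn")

depthRangeLabels <- function(breaks = c(0, 15, 30, 50, 100)) {
  paste0(breaks[-length(breaks)], "-", breaks[-1])
}

#' Assign a depth to an analysis depth range
#'
#' Half-open, right-closed binning over the standard analysis intervals
#' (0-15, 15-30, 30-50, 50-100 m). Depths beyond the last break (100 m, where
#' observations become too sparse for stratified statistics) map to `NA`.
#'
#' @param depth depth(s) in metres, strictly positive.
#' @param breaks increasing break points, metres.
#' @return character vector of range labels (`NA` beyond the last break).
#' @export
assignDepthRange <- function(depth, breaks = c(0, 15, 30, 50, 100)) {
  depth <- as.numeric(depth)
  if (anyNA(depth) || any(depth <= 0))
    stop("depth must be strictly positive", call. = FALSE)
  as.character(cut(depth, breaks = breaks, labels = depthRangeLabels(breaks),
                   include.lowest = FALSE, right = TRUE))
}

#' Construct / read a prioritised sub-region set
#'
#' `regionSet()` builds a [RegionSet-class] from named vertex matrices;
#' `readRegionSet()` loads one from a GeoJSON FeatureCollection whose
#' features carry a `name` property (feature order sets the priority);
#' `defaultRegionSet()` returns the Adriatic sub-regions shipped with the
#' package (WACC coastal band, then northern, middle and southern Adriatic;
#' documented approximations of bathymetry-based definitions).
#'
#' @param polygons named list of two-column (lon, lat) vertex matrices, in
#'   priority order.
#' @param path GeoJSON file path.
#' @return a [RegionSet-class].
#' @export
regionSet <- function(polygons) {
  obj <- new("RegionSet", names = names(polygons),
             polygons = lapply(polygons, function(p) {
               p <- as.matrix(p)
               dimnames(p) <- NULL
               p
             }))
  validObject(obj)
  obj
}

#' @rdname regionSet
#' @export
readRegionSet <- function(path) {
  if (!file.exists(path)) stop("regions file not found: ", path, call. = FALSE)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features))
    stop("regions file is not a GeoJSON FeatureCollection", call. = FALSE)
  polys <- list()
  for (f in gj$features) {
    nm <- f$properties$name
    if (is.null(nm)) stop("GeoJSON feature lacks a 'name' property",
                          call. = FALSE)
    if (!identical(f$geometry$type, "Polygon"))
      stop(sprintf("region '%s': only Polygon geometries are supported", nm),
           call. = FALSE)
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    polys[[nm]] <- m
  }
  regionSet(polys)
}

#' @rdname regionSet
#' @export
defaultRegionSet <- function() {
  readRegionSet(system.file("extdata", "adriatic_regions.geojson",
                            package = "diveTherm", mustWork = TRUE))
}

#' Assign points to sub-regions
#'
#' Point-in-polygon test against the region set, in priority order (the first
#' region containing the point wins); points outside every polygon are
#' labelled `"other"`.
#'
#' @param lat,lon coordinates in decimal degrees (vectorised).
#' @param regions a [RegionSet-class].
#' @return character vector of region names.
#' @export
assignSubregion <- function(lat, lon, regions) {
  pts <- cbind(lon, lat)
  out <- rep("other", nrow(pts))
  for (i in rev(seq_along(regions@names))) {
    inside <- mgcv::in.out(regions@polygons[[i]], pts)
    out[inside] <- regions@names[i]
  }
  out
}

## Index of the nearest sea cell to a point, great-circle distance,
## ties broken by lowest (lat index, lon index). Returns NULL when nothing
## is within maxKm.
nearestSeaCell <- function(lon, lat, field, maxKm = 25) {
  sea <- which(seaMask(field), arr.ind = TRUE)  # [latIdx, lonIdx]
  d <- haversineKm(fieldLons(field)[sea[, 2]], fieldLats(field)[sea[, 1]],
                   lon, lat)
  dmin <- min(d)
  if (dmin > maxKm) return(NULL)
  tied <- which(d <= dmin + 1e-9)
  pick <- tied[order(sea[tied, 1], sea[tied, 2])][1L]
  list(lat_idx = unname(sea[pick, 1]), lon_idx = unname(sea[pick, 2]),
       dist_km = d[pick])
}

#' Match a dive profile to the model grid
#'
#' Finds the sea cell whose centre minimises the great-circle distance to the
#' fix position (equidistant candidates broken by lowest lat then lon index)
#' and the daily field slice containing the profile's mid-dive timestamp.
#'
#' @param profile a [DiveProfile-class].
#' @param field a [GriddedField-class].
#' @param max_match_km unmatched if the nearest sea cell is farther than
#'   this (guards against fixes far outside the field domain).
#' @return `list(lat_idx, lon_idx, time_idx, dist_km)`, or `NULL` for
#'   unmatched profiles.
#' @export
matchProfileToGrid <- function(profile, field, max_match_km = 25) {
  m <- matchProfileImpl(profile, field, max_match_km)
  if (!m$ok) return(NULL)
  m[c("lat_idx", "lon_idx", "time_idx", "dist_km")]
}

matchProfileImpl <- function(profile, field, max_match_km = 25) {
  s <- diveSamples(profile)
  mid <- as.POSIXct(mean(range(as.numeric(s$utc))),
                    origin = "1970-01-01", tz = "UTC")
  date <- as.Date(mid, tz = "UTC")
  ti <- match(date, fieldDates(field))
  if (is.na(ti)) return(list(ok = FALSE, reason = "date_outside_field"))
  cell <- nearestSeaCell(fixLon(profile), fixLat(profile), field,
                         maxKm = max_match_km)
  if (is.null(cell))
    return(list(ok = FALSE, reason = "no_sea_cell_within_range"))
  list(ok = TRUE, reason = NA_character_, lat_idx = cell$lat_idx,
       lon_idx = cell$lon_idx, time_idx = ti, dist_km = cell$dist_km)
}

#' Collocate dive profiles with the gridded model product
#'
#' Profiles matched to the same model cell and daily slice are first averaged
#' depth-wise (mean of temperatures at identical sample depths, union of
#' depths otherwise) and then linearly interpolated onto the model's vertical
#' levels, restricted to the observed depth span (no extrapolation). A group
#' reduced to a single depth contributes only if a model level lies within
#' half the local model level spacing of that depth. Each covered level
#' yields one matched pair carrying season, depth-range and sub-region
#' strata.
#'
#' @param profiles a [DiveProfileList-class].
#' @param field a [GriddedField-class].
#' @param regions a [RegionSet-class] (default: the shipped Adriatic set).
#' @param max_match_km see [matchProfileToGrid()].
#' @param depth_breaks depth-range edges for stratification, metres.
#' @return `data.frame` of matched pairs: `tag_id`, `dive_id`, `date`,
#'   `lat`, `lon`, `depth_level`, `obs_temp`, `model_temp`, `season`,
#'   `depth_range` (`NA` beyond the last break), `subregion`, `n_obs` (raw
#'   samples behind the pair), `n_profiles`, plus cell indices. Attribute
#'   `unmatched` tabulates profiles that could not be matched, by reason.
#' @export
collocate <- function(profiles, field, regions = defaultRegionSet(),
                      max_match_km = 25, depth_breaks = c(0, 15, 30, 50, 100)) {
  levels <- fieldDepths(field)
  vals <- fieldValues(field)
  keys <- character(0)
  groups <- list()
  unmatched <- character(0)
  for (p in as.list(profiles)) {
    m <- matchProfileImpl(p, field, max_match_km = max_match_km)
    if (!m$ok) {
      unmatched <- c(unmatched, m$reason)
      next
    }
    key <- paste(m$time_idx, m$lat_idx, m$lon_idx, sep = "_")
    i <- match(key, keys)
    if (is.na(i)) {
      keys <- c(keys, key)
      groups[[length(groups) + 1L]] <- list(m = m, profiles = list(p))
    } else {
      groups[[i]]$profiles <- c(groups[[i]]$profiles, list(p))
    }
  }

  pairs <- list()
  for (g in groups) {
    m <- g$m
    s <- do.call(rbind, lapply(g$profiles, diveSamples))
    ## average-then-interpolate: mean at identical depths, union of depths
    agg <- stats::aggregate(temp_c ~ depth_m, data = s, FUN = mean)
    agg <- agg[order(agg$depth_m), ]
    covered <- levels >= min(agg$depth_m) & levels <= max(agg$depth_m)
    if (nrow(agg) >= 2L) {
      li <- which(covered)
      if (!length(li)) next
      obs <- stats::approx(agg$depth_m, agg$temp_c, xout = levels[li])$y
    } else {
      halfStep <- localLevelHalfSpacing(levels)
      li <- which(abs(levels - agg$depth_m) <= halfStep)
      if (!length(li)) next
      obs <- rep(agg$temp_c, length(li))
    }
    model <- vals[m$time_idx, li, m$lat_idx, m$lon_idx]
    date <- fieldDates(field)[m$time_idx]
    lat <- mean(vapply(g$profiles, fixLat, 0))
    lon <- mean(vapply(g$profiles, fixLon, 0))
    pairs[[length(pairs) + 1L]] <- data.frame(
      tag_id = paste(unique(vapply(g$profiles, tagId, "")), collapse = ";"),
      dive_id = paste(vapply(g$profiles, diveId, ""), collapse = ";"),
      date = date, lat = lat, lon = lon,
      depth_level = levels[li], obs_temp = obs, model_temp = model,
      season = assignSeason(date),
      depth_range = suppressWarnings(assignDepthRange(levels[li],
                                                      depth_breaks)),
      subregion = assignSubregion(lat, lon, regions),
      n_obs = nrow(s), n_profiles = length(g$profiles),
      time_idx = m$time_idx, lat_idx = m$lat_idx, lon_idx = m$lon_idx,
      stringsAsFactors = FALSE)
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else emptyPairs()
  out <- out[!is.na(out$model_temp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched") <- table(unmatched)
  out
}

localLevelHalfSpacing <- function(levels) {
  if (length(levels) < 2L) return(Inf)
  gaps <- diff(levels)
  half <- c(gaps[1], pmin(gaps[-length(gaps)], gaps[-1]), gaps[length(gaps)]) / 2
  half
}

emptyPairs <- function() {
  data.frame(tag_id = character(), dive_id = character(),
             date = as.Date(character()), lat = numeric(), lon = numeric(),
             depth_level = numeric(), obs_temp = numeric(),
             model_temp = numeric(), season = character(),
             depth_range = character(), subregion = character(),
             n_obs = integer(), n_profiles = integer(), time_idx = integer(),
             lat_idx = integer(), lon_idx = integer(),
             stringsAsFactors = FALSE)
}

#' Write / read a matched-pairs table
#'
#' @param pairs the `data.frame` from [collocate()].
#' @param path file path.
#' @return `writePairs` returns `path` invisibly; `readPairs` the pairs
#'   `data.frame`.
#' @export
writePairs <- function(pairs, path) {
  data.table::fwrite(pairs, path)
  invisible(path)
}

#' @rdname writePairs
#' @export
readPairs <- function(path) {
  ## na.strings = "" so the literal sub-region name "NA" survives the read
  df <- data.table::fread(path, data.table = FALSE, na.strings = "",
                          colClasses = list(character = c("tag_id", "dive_id",
                                                          "season",
                                                          "depth_range",
                                                          "subregion")))
  df$date <- as.Date(df$date)
  df$depth_range[df$depth_range == ""] <- NA_character_
  df
}
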