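## Shared fixtures, built in code at test time.

## Tiny gridded field with hand-settable values: constant temperature unless
## a values array is supplied.
tinyField <- function(dates = as.Date("2021-06-15"),
                      depths = c(5, 10, 20, 30),
                      lats = seq(40.0, 40.2, by = 0.1),
                      lons = seq(17.0, 17.2, by = 0.1),
                      temp = 20, mask = NULL, values = NULL) {
  dims <- c(length(dates), length(depths), length(lats), length(lons))
  if (is.null(values)) values <- array(temp, dim = dims)
  if (!is.null(mask)) {
    land <- which(!mask, arr.ind = TRUE)
    for (k in seq_len(nrow(land)))
      values[, , land[k, 1], land[k, 2]] <- NA_real_
  }
  griddedField(dates, depths, lats, lons, values, mask = mask)
}

## One-line constructors for raw tag rows (as parseTagFile would return them).
fixRecord <- function(tag = "T1", utc = "2021-06-15T12:00:00", lat = 40.1,
                      lon = 17.1, lq = "0", line = 2L) {
  out <- data.frame(tag_id = tag, row_type = "FIX", line = line,
                    stringsAsFactors = FALSE)
  out$utc <- as.POSIXct(utc, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  for (f in c("lat", "lon")) out[[f]] <- get(f)
  out$sst <- out$sst_time_min <- NA_real_
  for (f in paste0(c("d", "t"), rep(1:6, each = 2))) out[[f]] <- NA_real_
  out$dt_time_min <- NA_real_
  out$lq <- lq
  out[c("tag_id", "row_type", "line", "utc", "lat", "lon", "sst",
        "sst_time_min", paste0(c("d", "t"), rep(1:6, each = 2)),
        "dt_time_min", "lq")]
}

diveRecord <- function(tag = "T1", dt_time_min = 30,
                       depths = c(5, 10, 10, 5), temps = NULL, line = 3L) {
  if (is.null(temps)) temps <- 20 - 0.1 * depths
  out <- data.frame(tag_id = tag, row_type = "DIVE", line = line,
                    stringsAsFactors = FALSE)
  out$utc <- as.POSIXct(NA)
  out$lat <- out$lon <- NA_real_
  out$sst <- 21
  out$sst_time_min <- dt_time_min + 10
  for (i in 1:6) {
    out[[paste0("d", i)]] <- if (i <= length(depths)) depths[i] else NA_real_
    out[[paste0("t", i)]] <- if (i <= length(temps)) temps[i] else NA_real_
  }
  out$dt_time_min <- dt_time_min
  out$lq <- ""
  out[c("tag_id", "row_type", "line", "utc", "lat", "lon", "sst",
        "sst_time_min", paste0(c("d", "t"), rep(1:6, each = 2)),
        "dt_time_min", "lq")]
}

bindRecords <- function(...) {
  out <- do.call(rbind, list(...))
  attr(out, "n_rows") <- nrow(out)
  attr(out, "n_diag") <- 0L
  out
}

## A DiveProfile built directly, for matchup tests.
makeProfile <- function(tag = "T1", dive = "T1_0001",
                        fix_utc = as.POSIXct("2021-06-15T14:00:00",
                                             format = "%Y-%m-%dT%H:%M:%S",
                                             tz = "UTC"),
                        lat = 40.1, lon = 17.1, lq = "0",
                        depths = c(5, 10, 20, 30), temps = NULL,
                        t_start = fix_utc - 3600) {
  if (is.null(temps)) temps <- 22 - 0.1 * depths
  new("DiveProfile", tagId = tag, diveId = dive, fixUtc = fix_utc,
      lat = lat, lon = lon, lq = lq,
      samples = data.frame(
        utc = t_start + 300 * (seq_along(depths) - 1),
        depth_m = depths, temp_c = temps))
}

profileList <- function(...) {
  new("DiveProfileList", S4Vectors::SimpleList(list(...)))
}

## Small region set: a high-priority inner square inside a larger square.
toyRegions <- function() {
  regionSet(list(
    inner = cbind(c(1, 2, 2, 1), c(1, 1, 2, 2)),
    outer = cbind(c(0, 3, 3, 0), c(0, 0, 3, 3))))
}

## Synthetic matched pairs with a tunable correlation and bias, for the
## statistics tests.
mkPairs <- function(n, season = "spring", depth_range = "0-15",
                    subregion = "SA", r_target = 0.95, bias = 0.3,
                    depth_level = 10) {
  obs <- rnorm(n, 18, 2)
  model <- r_target * (obs - 18) + sqrt(1 - r_target^2) * rnorm(n, 0, 2) +
    18 + bias
  data.frame(obs_temp = obs, model_temp = model, season = season,
             depth_range = depth_range, subregion = subregion,
             depth_level = depth_level, n_obs = 3L,
             stringsAsFactors = FALSE)
}

## One catch-all region covering the whole north-east quadrant, for tests
## where the stratum label itself is irrelevant.
toyRegionsWide <- function() {
  regionSet(list(box = cbind(c(0, 180, 180, 0), c(0, 0, 90, 90))))
}

## A compact pipeline config for end-to-end tests.
smallRunConfig <- function(seed = 5, ...) {
  base <- list(
    seed = seed, out_dir = tempfile("dtrun"),
    dates = list(start = "2021-02-01", end = "2021-11-30"),
    turtles = list(n_turtles = 3, n_dives_per_turtle = 25),
    argo = list(n_profiles = 15))
  user <- list(...)
  for (k in names(user))
    base[[k]] <- utils::modifyList(base[[k]] %||% list(), user[[k]])
  validateConfig(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
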