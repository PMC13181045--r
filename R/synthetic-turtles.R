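## Argos location quality classes and the nominal position error (sd, metres)
## used when perturbing simulated fix positions. Class 0 follows the tag
## manufacturer's ~1,500 m estimate; poorer classes get larger errors,
## better classes smaller ones.
lqClasses <- function() c("Z", "B", "A", "0", "1", "2", "3")

lqErrorSd <- function() {
  c(Z = 10000, B = 6000, A = 3000, `0` = 1500, `1` = 1000, `2` = 500, `3` = 250)
}

#' Parameters of the turtle dive simulator
#'
#' Dives are trapezoidal (descent, bottom, ascent) with depth and temperature
#' sampled on the tag's 5-minute lattice. Maximum dive depth follows a
#' right-truncated exponential distribution hard-capped at `depth_max`
#' (175 m, the deepest dive the tags can report in this configuration), and
#' dive duration is coupled to depth (deep dives are long resting dives)
#' and hard-capped at `duration_max` (240 min, the tag's storage limit).
#' Each turtle performs one dive per deployment day and transmits after
#' surfacing; the post-dive Argos fix carries a location quality class drawn
#' from `lq_probabilities` and a position perturbed by the class-typical
#' error (1,500 m sd at LQ 0).
#'
#' @param n_turtles number of tagged animals.
#' @param n_dives_per_turtle dives (= deployment days) per animal.
#' @param bbox named list `lon_min`, `lon_max`, `lat_min`, `lat_max`.
#' @param depth_scale mean of the exponential depth distribution, m.
#' @param depth_min,depth_max dive depth bounds, m (`depth_max` <= 175).
#' @param duration_max maximum dive duration, minutes (<= 240).
#' @param minutes_per_metre minimum dive duration per metre of maximum depth;
#'   controls the vertical spacing of the 5-min samples.
#' @param sample_interval sampling interval, minutes (must divide 30).
#' @param lq_probabilities named probability vector over the Argos classes
#'   Z, B, A, 0, 1, 2, 3. The default puts half the mass on class 0 so the
#'   downstream location-quality filter is exercised.
#' @param lq0_position_error_sd position error sd for class 0 fixes, metres.
#' @param obs_noise_sd sensor noise added to sampled temperatures, degC.
#' @param transmission_prob probability a dive is transmitted (the tags'
#'   duty cycle is not documented; default transmits everything).
#' @param seed integer seed.
#' @return a validated parameter list of class `TurtleSimParams`.
#' @export
turtleSimParams <- function(n_turtles = 7, n_dives_per_turtle = 45,
                            bbox = list(lon_min = 16.8, lon_max = 18.4,
                                        lat_min = 40.3, lat_max = 41.8),
                            depth_scale = 25, depth_min = 5, depth_max = 175,
                            duration_max = 240, minutes_per_metre = 2.4,
                            sample_interval = 5,
                            lq_probabilities = c(Z = 0.05, B = 0.1, A = 0.1,
                                                 `0` = 0.5, `1` = 0.1,
                                                 `2` = 0.1, `3` = 0.05),
                            lq0_position_error_sd = 1500,
                            obs_noise_sd = 0, transmission_prob = 1,
                            seed = 1L) {
  stopifnot(n_turtles >= 1, n_dives_per_turtle >= 1,
            depth_max <= 175, duration_max <= 240,
            30 %% sample_interval == 0, sample_interval > 0,
            obs_noise_sd >= 0, transmission_prob >= 0, transmission_prob <= 1)
  lq_probabilities <- lq_probabilities[lqClasses()]
  if (anyNA(lq_probabilities) || abs(sum(lq_probabilities) - 1) > 1e-8)
    stop("lq_probabilities must cover Z,B,A,0,1,2,3 and sum to 1",
         call. = FALSE)
  structure(list(n_turtles = n_turtles,
                 n_dives_per_turtle = n_dives_per_turtle, bbox = as.list(bbox),
                 depth_scale = depth_scale, depth_min = depth_min,
                 depth_max = depth_max, duration_max = duration_max,
                 minutes_per_metre = minutes_per_metre,
                 sample_interval = sample_interval,
                 lq_probabilities = lq_probabilities,
                 lq0_position_error_sd = lq0_position_error_sd,
                 obs_noise_sd = obs_noise_sd,
                 transmission_prob = transmission_prob,
                 seed = as.integer(seed)),
            class = "TurtleSimParams")
}

## Trapezoidal dive shape: fraction of maximum depth at phase u in (0, 1).
trapezoidDepth <- function(u, f_desc = 0.35, f_asc = 0.35) {
  d <- rep(1, length(u))
  d[u < f_desc] <- u[u < f_desc] / f_desc
  hi <- u > 1 - f_asc
  d[hi] <- (1 - u[hi]) / f_asc
  d
}

#' Simulate turtle dives against the known-truth field
#'
#' Each turtle starts at a random position inside `bbox`, performs a daily
#' random-walk, and dives once per day between 06:00 and 16:00 UTC (dives
#' never straddle a civil date boundary). Depth-temperature samples sit on
#' the tag's 5-minute lattice; temperatures are the truth field evaluated at
#' the sample depth, date and the turtle's true latitude (plus optional
#' sensor noise). Each dive ends with a satellite fix whose position is the
#' true position perturbed by the drawn location-quality class error.
#'
#' @param params a [turtleSimParams()] list.
#' @param truth an [oceanTruthParams()] list.
#' @param dates `Date` vector: the window deployments are placed in.
#' @return a list of simulated dives (class `simulatedDives`); each element
#'   carries tag id, true and fix positions, LQ class, sample table
#'   (`utc`, `depth_m`, `temp_c`), SST metadata and the fix time.
#' @export
simulateTurtleDives <- function(params, truth, dates) {
  dates <- as.Date(dates)
  if (length(dates) < 1L) stop("empty date window", call. = FALSE)
  b <- params$bbox
  if (b$lon_max <= b$lon_min || b$lat_max <= b$lat_min)
    stop("bbox outside field domain or degenerate", call. = FALSE)
  span <- as.integer(max(dates) - min(dates)) + 1L
  nd <- params$n_dives_per_turtle
  if (span < nd)
    stop("date window shorter than the deployment length", call. = FALSE)
  si <- params$sample_interval
  errSd <- lqErrorSd()
  errSd["0"] <- params$lq0_position_error_sd

  withr::with_seed(params$seed, {
    dives <- vector("list", params$n_turtles * nd)
    k <- 0L
    for (tu in seq_len(params$n_turtles)) {
      tag <- sprintf("SYN%03d", 200 + tu)
      start <- min(dates) + sample.int(span - nd + 1L, 1L) - 1L
      lon <- stats::runif(1, b$lon_min + 0.1 * (b$lon_max - b$lon_min),
                          b$lon_max - 0.1 * (b$lon_max - b$lon_min))
      lat <- stats::runif(1, b$lat_min + 0.1 * (b$lat_max - b$lat_min),
                          b$lat_max - 0.1 * (b$lat_max - b$lat_min))
      for (dv in seq_len(nd)) {
        day <- start + dv - 1L
        ## ~8 km daily random-walk step, reflected into the box
        lon <- min(max(lon + stats::rnorm(1, 0, 0.07), b$lon_min), b$lon_max)
        lat <- min(max(lat + stats::rnorm(1, 0, 0.07), b$lat_min), b$lat_max)
        maxDepth <- min(params$depth_min + stats::rexp(1, 1 / params$depth_scale),
                        params$depth_max)
        durMin <- max(4 * si, params$minutes_per_metre * maxDepth)
        dur <- min(params$duration_max,
                   si * ceiling((durMin + stats::runif(1, 0, 60)) / si))
        n <- as.integer(dur / si)
        t0 <- as.POSIXct(day, tz = "UTC") +
          3600 * sample(6:15, 1L) + 60 * si * sample.int(6L, 1L)
        sampleUtc <- t0 + 60 * si * (seq_len(n) - 1L)
        depths <- maxDepth * trapezoidDepth((seq_len(n) - 0.5) / n)
        temps <- truthTemperature(depths, day, lat, truth)
        if (params$obs_noise_sd > 0)
          temps <- temps + stats::rnorm(n, 0, params$obs_noise_sd)
        surfGap <- 60 * si * sample(2:10, 1L)
        fixUtc <- sampleUtc[n] + surfGap
        lq <- sample(names(params$lq_probabilities), 1L,
                     prob = params$lq_probabilities)
        e <- errSd[[lq]]
        fixLat <- lat + stats::rnorm(1, 0, e) / 111320
        fixLon <- lon + stats::rnorm(1, 0, e) / (111320 * cos(lat * pi / 180))
        sst <- truthTemperature(0.5, day, lat, truth)
        k <- k + 1L
        dives[[k]] <- list(
          tag_id = tag, date = day, true_lat = lat, true_lon = lon,
          fix_lat = fixLat, fix_lon = fixLon, lq = lq, fix_utc = fixUtc,
          samples = data.frame(utc = sampleUtc, depth_m = depths,
                               temp_c = temps),
          sst = sst,
          sst_time_min = as.numeric(difftime(fixUtc, t0 - 60 * si,
                                             units = "mins")),
          transmitted = stats::runif(1) < params$transmission_prob)
      }
    }
    structure(dives, class = "simulatedDives")
  })
}

#' Encode simulated dives into the tag CSV dialect
#'
#' Writes one file per tag. Each transmitted dive is emitted as a `FIX` row
#' (tag id, UTC, lat, lon, LQ) followed by its `DIVE` record rows, most
#' recent record first as the tag transmits them. A record holds up to six
#' depth-temperature pairs (30 min of observations at 5-min spacing), the
#' surface temperature and its elapsed time before transmission (`sst`,
#' `sst_time_min`) at the start, and the elapsed minutes between the record's
#' most recent pair and the transmission (`dt_time_min`) as the trailer.
#' Optional `DIAG` rows with battery diagnostics are interleaved.
#'
#' @param dives a `simulatedDives` list from [simulateTurtleDives()].
#' @param dir output directory (created if needed).
#' @param diag_every insert one diagnostic row per this many dives
#'   (`0` = none).
#' @return invisibly, the written file paths (named by tag id).
#' @export
encodeTagFiles <- function(dives, dir, diag_every = 8L) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create tag output directory: ", dir, call. = FALSE)
  tags <- vapply(dives, `[[`, "", "tag_id")
  paths <- character(0)
  for (tag in unique(tags)) {
    rows <- list()
    nDive <- 0L
    for (d in dives[tags == tag]) {
      if (!isTRUE(d$transmitted)) next
      nDive <- nDive + 1L
      rows[[length(rows) + 1L]] <- tagRow(
        tag, "FIX", utc = d$fix_utc, lat = d$fix_lat, lon = d$fix_lon,
        lq = d$lq)
      s <- d$samples
      n <- nrow(s)
      blockStart <- seq(1L, n, by = 6L)
      ## most recent record first, as transmitted
      for (bs in rev(blockStart)) {
        be <- min(bs + 5L, n)
        dt <- as.numeric(difftime(d$fix_utc, s$utc[be], units = "mins"))
        pairs <- rep(NA_real_, 12L)
        m <- be - bs + 1L
        pairs[2 * seq_len(m) - 1] <- s$depth_m[bs:be]
        pairs[2 * seq_len(m)] <- s$temp_c[bs:be]
        rows[[length(rows) + 1L]] <- tagRow(
          tag, "DIVE", sst = d$sst, sst_time_min = d$sst_time_min,
          pairs = pairs, dt_time_min = dt)
      }
      if (diag_every > 0L && nDive %% diag_every == 0L)
        rows[[length(rows) + 1L]] <- tagRow(tag, "DIAG", diag = "BATT=3.61V")
    }
    path <- file.path(dir, paste0(tag, ".csv"))
    con <- tryCatch(file(path, "w"), error = function(e)
      stop("cannot write tag file: ", path, call. = FALSE))
    writeLines(c(tagHeader(), unlist(rows)), con)
    close(con)
    paths[tag] <- path
  }
  invisible(paths)
}

tagHeader <- function() {
  paste(c("tag_id", "row_type", "utc", "lat", "lon", "lq", "sst",
          "sst_time_min", paste0(c("d", "t"), rep(1:6, each = 2)),
          "dt_time_min"), collapse = ",")
}

tagRow <- function(tag, type, utc = NA, lat = NA, lon = NA, lq = "",
                   sst = NA, sst_time_min = NA, pairs = rep(NA_real_, 12L),
                   dt_time_min = NA, diag = "") {
  if (type == "DIAG") {
    return(paste(c(tag, "DIAG", diag, rep("", 18L)), collapse = ","))
  }
  paste(c(tag, type, formatUtc(utc), numToChar(lat), numToChar(lon), lq,
          numToChar(sst), numToChar(sst_time_min), numToChar(pairs),
          numToChar(dt_time_min)), collapse = ",")
}

#' Simulate ARGO-style float profiles
#'
#' Profiles sampled at 1-m vertical resolution from the surface down to
#' `max_depth`, at random positions/dates inside the window, with independent
#' Gaussian sensor noise on top of the truth field.
#'
#' @param n_profiles number of profiles.
#' @param truth an [oceanTruthParams()] list.
#' @param bbox named list `lon_min`, `lon_max`, `lat_min`, `lat_max`.
#' @param dates `Date` vector: candidate profile dates.
#' @param max_depth deepest sample, m.
#' @param noise_sd sensor noise sd, degC (>= 0).
#' @param seed integer seed.
#' @return `data.frame` with columns `platform_id`, `utc`, `lat`, `lon`,
#'   `depth_m`, `temp_c`.
#' @export
simulateArgoProfiles <- function(n_profiles, truth, bbox, dates,
                                 max_depth = 40, noise_sd = 0.05, seed = 1L) {
  stopifnot(n_profiles >= 1, max_depth >= 1, noise_sd >= 0)
  dates <- as.Date(dates)
  b <- as.list(bbox)
  withr::with_seed(as.integer(seed), {
    out <- vector("list", n_profiles)
    depths <- 0:floor(max_depth)
    for (i in seq_len(n_profiles)) {
      lon <- stats::runif(1, b$lon_min, b$lon_max)
      lat <- stats::runif(1, b$lat_min, b$lat_max)
      day <- sample(dates, 1L)
      utc <- as.POSIXct(day, tz = "UTC") + 3600 * sample(0:23, 1L)
      temps <- truthTemperature(depths, day, lat, truth)
      if (noise_sd > 0) temps <- temps + stats::rnorm(length(depths), 0, noise_sd)
      out[[i]] <- data.frame(
        platform_id = sprintf("SYNARGO%04d", 6900 + i),
        utc = utc, lat = lat, lon = lon, depth_m = depths, temp_c = temps)
    }
    do.call(rbind, out)
  })
}
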