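## Tag CSV dialect decoding: parse -> fix filtering -> dive segmentation ->
## retroactive time reconstruction and quality control.

pairCols <- function() paste0(c("d", "t"), rep(1:6, each = 2))

#' Parse a tag transmission file
#'
#' Reads the tag CSV dialect, drops diagnostic (`DIAG`) rows, validates the
#' numeric and timestamp fields of the remaining rows, and returns them in
#' file order. Malformed rows (wrong arity, unparseable numbers or dates)
#' raise a parse error naming the offending line.
#'
#' @param path path to a tag CSV file.
#' @return a `data.frame` of records (`FIX` and `DIVE` rows) with parsed
#'   columns, a `line` column holding original file line numbers, and
#'   attributes `n_rows` (data rows read) and `n_diag` (diagnostic rows
#'   dropped).
#' @export
parseTagFile <- function(path) {
  if (!file.exists(path)) stop("tag file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, colClasses = "character", header = TRUE,
                           fill = TRUE, data.table = FALSE)
  expected <- strsplit(tagHeader(), ",")[[1]]
  if (!identical(names(raw), expected))
    stop("tag file header does not match the tag CSV dialect: ", path,
         call. = FALSE)
  if (nrow(raw) == 0L) {
    warning("tag file contains no records: ", path, call. = FALSE)
    out <- emptyRecords()
    attr(out, "n_rows") <- 0L
    attr(out, "n_diag") <- 0L
    return(out)
  }
  raw$line <- seq_len(nrow(raw)) + 1L  # line 1 is the header
  bad <- !raw$row_type %in% c("FIX", "DIVE", "DIAG")
  if (any(bad))
    stop(sprintf("parse error at line %d: unknown row_type '%s'",
                 raw$line[which(bad)[1]], raw$row_type[which(bad)[1]]),
         call. = FALSE)
  nDiag <- sum(raw$row_type == "DIAG")
  rec <- raw[raw$row_type != "DIAG", , drop = FALSE]

  out <- data.frame(tag_id = rec$tag_id, row_type = rec$row_type,
                    line = rec$line, stringsAsFactors = FALSE)
  out$utc <- parseUtc(rec$utc)
  unparsed <- nzchar(trimws(rec$utc)) & is.na(out$utc)
  if (any(unparsed))
    stop(sprintf("parse error at line %d: bad timestamp '%s'",
                 rec$line[which(unparsed)[1]], rec$utc[which(unparsed)[1]]),
         call. = FALSE)
  for (f in c("lat", "lon", "sst", "sst_time_min", pairCols(), "dt_time_min"))
    out[[f]] <- numFromChar(rec[[f]], rec$line, f)
  out$lq <- trimws(rec$lq)
  attr(out, "n_rows") <- nrow(raw)
  attr(out, "n_diag") <- nDiag
  out
}

emptyRecords <- function() {
  out <- data.frame(tag_id = character(), row_type = character(),
                    line = integer(), stringsAsFactors = FALSE)
  out$utc <- as.POSIXct(character(), tz = "UTC")
  for (f in c("lat", "lon", "sst", "sst_time_min", pairCols(), "dt_time_min"))
    out[[f]] <- numeric()
  out$lq <- character()
  out
}

#' Filter records by fix validity and Argos location quality
#'
#' Removes every `FIX` row -- together with all `DIVE` rows attributed to it
#' (the rows following it up to the next fix) -- unless the fix has valid
#' coordinates, a location quality class, and that class is in `allowed_lq`.
#' The default retains only class 0 (nominal precision ~1,500 m, consistent
#' with a ~4 km model grid).
#'
#' @param records a parsed record `data.frame` from [parseTagFile()].
#' @param allowed_lq character vector of admitted classes (subset of
#'   Z, B, A, 0, 1, 2, 3).
#' @return the retained records, with attribute `filter_counts`: dive rows
#'   removed by the LQ filter (`n_dive_rows_lq`), by invalid fixes
#'   (`n_dive_rows_invalid_fix`), and the numbers of fixes removed for each
#'   reason.
#' @export
filterFixes <- function(records, allowed_lq = "0") {
  allowed_lq <- as.character(allowed_lq)
  if (!all(allowed_lq %in% lqClasses()))
    stop("unknown LQ class in allowed_lq: ",
         paste(setdiff(allowed_lq, lqClasses()), collapse = ", "),
         call. = FALSE)
  isFix <- records$row_type == "FIX"
  lqSeen <- records$lq[isFix]
  known <- lqSeen %in% lqClasses() | !nzchar(lqSeen)
  if (!all(known))
    stop("unknown LQ symbol in fix records: ", lqSeen[!known][1],
         call. = FALSE)
  fixGroup <- cumsum(isFix)
  fixRows <- which(isFix)
  valid <- !is.na(records$lat[fixRows]) & !is.na(records$lon[fixRows]) &
    nzchar(records$lq[fixRows]) & !is.na(records$utc[fixRows])
  admitted <- valid & records$lq[fixRows] %in% allowed_lq
  ## group 0 = dive rows before any fix; kept here, dropped at segmentation
  keepGroup <- c(TRUE, admitted)[fixGroup + 1L]
  groupOfRow <- fixGroup
  removedInvalid <- which(!valid)
  removedLq <- which(valid & !admitted)
  diveRows <- !isFix
  counts <- c(
    n_fix_invalid = length(removedInvalid),
    n_fix_lq = length(removedLq),
    n_dive_rows_invalid_fix =
      sum(diveRows & groupOfRow %in% removedInvalid),
    n_dive_rows_lq = sum(diveRows & groupOfRow %in% removedLq))
  out <- records[keepGroup, , drop = FALSE]
  for (a in c("n_rows", "n_diag")) attr(out, a) <- attr(records, a)
  attr(out, "filter_counts") <- counts
  out
}

## Reconstructed time range of one DIVE record row, seconds since epoch.
## The trailer dt_time_min anchors the record's most recent pair; earlier
## pairs step back on the sampling lattice.
recordTimeRange <- function(fixUtc, dtMin, nPairs, interval = 5) {
  end <- as.numeric(fixUtc) - 60 * dtMin
  c(start = end - 60 * interval * (nPairs - 1), end = end)
}

nPopulatedPairs <- function(row) {
  dcols <- paste0("d", 1:6)
  tcols <- paste0("t", 1:6)
  sum(!is.na(unlist(row[dcols])) | !is.na(unlist(row[tcols])))
}

#' Group dive records into individual dive events
#'
#' Attributes each `DIVE` row to the preceding `FIX` row, reconstructs each
#' record's time range from its `dt_time_min` trailer, and splits a fix's
#' records into dives wherever consecutive (time-ordered) records are not
#' contiguous on the sampling lattice: a gap of more than one sampling
#' interval starts a new dive. `DIVE` rows with no preceding fix are dropped
#' with a warning.
#'
#' @param records filtered records from [filterFixes()].
#' @param interval sampling interval in minutes.
#' @return a list of groups, each `list(fix = <one-row data.frame>,
#'   rows = <DIVE rows data.frame>)`; attribute `n_orphan_dive_rows` counts
#'   dropped unattributed rows.
#' @export
segmentDives <- function(records, interval = 5) {
  isFix <- records$row_type == "FIX"
  fixGroup <- cumsum(isFix)
  orphans <- sum(!isFix & fixGroup == 0L)
  if (orphans > 0L)
    warning(sprintf("%d DIVE row(s) with no preceding FIX dropped", orphans),
            call. = FALSE)
  groups <- list()
  for (g in seq_len(max(fixGroup, 0L))) {
    rows <- records[fixGroup == g, , drop = FALSE]
    fix <- rows[1L, , drop = FALSE]
    dv <- rows[-1L, , drop = FALSE]
    if (nrow(dv) == 0L) next
    np <- vapply(seq_len(nrow(dv)), function(i) nPopulatedPairs(dv[i, ]), 0)
    ranges <- t(vapply(seq_len(nrow(dv)), function(i)
      recordTimeRange(fix$utc, dv$dt_time_min[i], max(np[i], 1L), interval),
      c(start = 0, end = 0)))
    ## records whose range cannot be reconstructed form their own group and
    ## are rejected downstream with a reason code
    bad <- is.na(dv$dt_time_min)
    for (i in which(bad))
      groups[[length(groups) + 1L]] <- list(fix = fix,
                                            rows = dv[i, , drop = FALSE])
    ok <- which(!bad)
    if (!length(ok)) next
    ord <- ok[order(ranges[ok, "start"])]
    newDive <- c(TRUE, ranges[ord[-1L], "start"] -
                   ranges[ord[-length(ord)], "end"] > 60 * interval + 1e-6)
    diveIdx <- cumsum(newDive)
    for (d in unique(diveIdx))
      groups[[length(groups) + 1L]] <-
        list(fix = fix, rows = dv[ord[diveIdx == d], , drop = FALSE])
  }
  attr(groups, "n_orphan_dive_rows") <- orphans
  groups
}

#' Reconstruct one dive profile from a record group
#'
#' Sample times are reconstructed retroactively: within each record, the pair
#' anchored by the `dt_time_min` trailer gets time `fix_utc - dt_time_min`,
#' and each earlier pair steps back by one sampling interval. Merged samples
#' are then checked for temporal coherence: if the sequence is not strictly
#' increasing, it is truncated, keeping (by default) the coherent run ending
#' at the most recent sample (`truncate = "suffix"`; `"prefix"` instead keeps
#' the run starting at the earliest sample). Samples at exactly 0 m depth
#' (surfacing; the sensor may read air temperature) are discarded. The dive
#' is rejected -- with a reason code, never an error -- if a populated pair
#' lacks depth or temperature, if a record's time trailer is missing, or if
#' fewer than two samples survive (no discernible start and end).
#'
#' @param group one element of the [segmentDives()] result.
#' @param interval sampling interval, minutes.
#' @param truncate `"suffix"` (keep the most recent coherent run) or
#'   `"prefix"` (keep the earliest).
#' @param dive_id identifier given to the resulting profile.
#' @return a list: `status` (`"ok"` or `"rejected"`), `profile`
#'   (a [DiveProfile-class] or `NULL`), `reason` (code for rejections),
#'   `n_samples_in`, `n_zero_depth`, `n_truncated`.
#' @export
reconstructDiveProfile <- function(group, interval = 5,
                                   truncate = c("suffix", "prefix"),
                                   dive_id = "d1") {
  truncate <- match.arg(truncate)
  fix <- group$fix
  rows <- group$rows
  rej <- function(reason, nIn = 0L)
    list(status = "rejected", profile = NULL, reason = reason,
         n_samples_in = nIn, n_zero_depth = 0L, n_truncated = 0L)
  if (is.na(fix$utc)) return(rej("missing_fix_time"))
  if (nrow(rows) == 0L) return(rej("no_samples"))
  if (anyNA(rows$dt_time_min)) return(rej("missing_time"))

  samples <- list()
  for (i in seq_len(nrow(rows))) {
    d <- unlist(rows[i, paste0("d", 1:6)])
    tm <- unlist(rows[i, paste0("t", 1:6)])
    pop <- which(!is.na(d) | !is.na(tm))
    if (!length(pop)) next
    if (anyNA(d[pop]) || anyNA(tm[pop])) return(rej("missing_values"))
    k <- max(pop)
    end <- as.numeric(fix$utc) - 60 * rows$dt_time_min[i]
    times <- end - 60 * interval * (k - pop)
    samples[[length(samples) + 1L]] <-
      data.frame(t = times, depth_m = unname(d[pop]), temp_c = unname(tm[pop]))
  }
  if (!length(samples)) return(rej("no_samples"))
  s <- do.call(rbind, samples)
  nIn <- nrow(s)

  keep <- coherentRun(s$t, truncate)
  nTrunc <- nIn - length(keep)
  s <- s[keep, , drop = FALSE]

  zero <- s$depth_m == 0
  nZero <- sum(zero)
  s <- s[!zero, , drop = FALSE]

  if (nrow(s) < 2L)
    return(within(rej("too_few_samples", nIn), {
      n_zero_depth <- nZero; n_truncated <- nTrunc
    }))
  profile <- new("DiveProfile",
                 tagId = fix$tag_id, diveId = dive_id,
                 fixUtc = fix$utc, lat = fix$lat, lon = fix$lon, lq = fix$lq,
                 samples = data.frame(
                   utc = as.POSIXct(s$t, origin = "1970-01-01", tz = "UTC"),
                   depth_m = s$depth_m, temp_c = s$temp_c))
  list(status = "ok", profile = profile, reason = NA_character_,
       n_samples_in = nIn, n_zero_depth = nZero, n_truncated = nTrunc)
}

## Temporal-coherence truncation. "suffix": drop samples not strictly earlier
## than the most recent one, then scan forward keeping a strictly increasing
## run that ends at the most recent sample (duplicate timestamps count as
## incoherent). "prefix": keep the increasing run starting at the first
## sample, stopping at the first inversion.
coherentRun <- function(t, truncate = "suffix") {
  n <- length(t)
  if (n <= 1L) return(seq_len(n))
  if (truncate == "prefix") {
    stopAt <- which(diff(t) <= 0)
    upto <- if (length(stopAt)) stopAt[1L] else n
    return(seq_len(upto))
  }
  cand <- c(which(t[-n] < t[n]), n)
  keep <- cand[1L]
  last <- t[keep]
  for (i in cand[-1L]) {
    if (t[i] > last) {
      keep <- c(keep, i)
      last <- t[i]
    }
  }
  keep
}

#' Decode a tag file into quality-controlled dive profiles
#'
#' Runs the full decoding chain: [parseTagFile()], [filterFixes()],
#' [segmentDives()], [reconstructDiveProfile()]. Every candidate dive is
#' accounted for: it either becomes a profile or contributes a reason-coded
#' rejection, and per-file counts reconcile parsed rows against profiles,
#' rejections and filter drops.
#'
#' @param path tag CSV file.
#' @param allowed_lq admitted Argos classes (default class 0 only).
#' @param truncate temporal-coherence truncation mode, see
#'   [reconstructDiveProfile()].
#' @param interval sampling interval, minutes.
#' @return a list with `profiles` (a [DiveProfileList-class]), `rejections`
#'   (`data.frame` of reason-coded rejected dives) and `counts` (named list:
#'   rows parsed, diagnostic/filtered/orphan drops, candidate dives,
#'   profiles, rejections, zero-depth and truncated samples).
#' @export
decodeTagFile <- function(path, allowed_lq = "0",
                          truncate = c("suffix", "prefix"), interval = 5) {
  truncate <- match.arg(truncate)
  parsed <- parseTagFile(path)
  filtered <- filterFixes(parsed, allowed_lq = allowed_lq)
  fc <- attr(filtered, "filter_counts")
  groups <- segmentDives(filtered, interval = interval)
  profiles <- list()
  rejections <- list()
  nZero <- 0L
  nTrunc <- 0L
  for (i in seq_along(groups)) {
    tag <- groups[[i]]$fix$tag_id
    res <- reconstructDiveProfile(groups[[i]], interval = interval,
                                  truncate = truncate,
                                  dive_id = sprintf("%s_%04d", tag, i))
    nZero <- nZero + res$n_zero_depth
    nTrunc <- nTrunc + res$n_truncated
    if (res$status == "ok") {
      profiles[[length(profiles) + 1L]] <- res$profile
    } else {
      rejections[[length(rejections) + 1L]] <- data.frame(
        tag_id = tag, dive_id = sprintf("%s_%04d", tag, i),
        reason = res$reason, stringsAsFactors = FALSE)
    }
  }
  rejections <- if (length(rejections)) do.call(rbind, rejections) else
    data.frame(tag_id = character(), dive_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  counts <- list(
    n_rows = attr(parsed, "n_rows"), n_diag = attr(parsed, "n_diag"),
    n_fix_invalid = unname(fc["n_fix_invalid"]),
    n_fix_lq = unname(fc["n_fix_lq"]),
    n_dive_rows_invalid_fix = unname(fc["n_dive_rows_invalid_fix"]),
    n_dive_rows_lq = unname(fc["n_dive_rows_lq"]),
    n_orphan_dive_rows = attr(groups, "n_orphan_dive_rows"),
    n_candidate_dives = length(groups),
    n_profiles = length(profiles),
    n_rejected = nrow(rejections),
    n_zero_depth_samples = nZero,
    n_truncated_samples = nTrunc)
  list(profiles = new("DiveProfileList",
                      S4Vectors::SimpleList(profiles)),
       rejections = rejections, counts = counts)
}

#' Decode all tag files in a directory
#'
#' @param dir directory of tag CSV files (`*.csv`).
#' @inheritParams decodeTagFile
#' @return as [decodeTagFile()], pooled over files, plus `per_file` counts.
#' @export
decodeTagDirectory <- function(dir, allowed_lq = "0",
                               truncate = c("suffix", "prefix"),
                               interval = 5) {
  truncate <- match.arg(truncate)
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop("no tag files found in ", dir, call. = FALSE)
  all <- lapply(files, decodeTagFile, allowed_lq = allowed_lq,
                truncate = truncate, interval = interval)
  profiles <- do.call(c, lapply(all, function(x) as.list(x$profiles)))
  counts <- Reduce(function(a, b) Map(`+`, a, b), lapply(all, `[[`, "counts"))
  list(profiles = new("DiveProfileList", S4Vectors::SimpleList(profiles)),
       rejections = do.call(rbind, lapply(all, `[[`, "rejections")),
       counts = counts,
       per_file = stats::setNames(lapply(all, `[[`, "counts"),
                                  basename(files)))
}

#' Flatten dive profiles into a samples table
#'
#' @param profiles a [DiveProfileList-class].
#' @return `data.frame` with one row per sample: `tag_id`, `dive_id`, `utc`,
#'   `lat`, `lon`, `lq`, `depth_m`, `temp_c`.
#' @export
profilesToDataFrame <- function(profiles) {
  if (!length(profiles))
    return(data.frame(tag_id = character(), dive_id = character(),
                      utc = as.POSIXct(character(), tz = "UTC"),
                      lat = numeric(), lon = numeric(), lq = character(),
                      depth_m = numeric(), temp_c = numeric()))
  do.call(rbind, lapply(as.list(profiles), function(p) {
    s <- diveSamples(p)
    data.frame(tag_id = tagId(p), dive_id = diveId(p), utc = s$utc,
               lat = fixLat(p), lon = fixLon(p), lq = locationQuality(p),
               depth_m = s$depth_m, temp_c = s$temp_c,
               stringsAsFactors = FALSE)
  }))
}

#' Write / read a decoded profiles table
#'
#' CSV with one row per sample, timestamps in ISO-8601 UTC.
#' @param profiles a [DiveProfileList-class] or the `data.frame` from
#'   [profilesToDataFrame()].
#' @param path file path.
#' @return `writeProfiles` returns `path` invisibly; `readProfiles` the
#'   samples `data.frame`.
#' @export
writeProfiles <- function(profiles, path) {
  df <- if (is.data.frame(profiles)) profiles else
    profilesToDataFrame(profiles)
  df$utc <- formatUtc(df$utc)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname writeProfiles
#' @export
readProfiles <- function(path) {
  df <- data.table::fread(path, data.table = FALSE,
                          colClasses = list(character = c("tag_id", "dive_id",
                                                          "utc", "lq")))
  df$utc <- parseUtc(df$utc)
  df
}
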