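truth <- oceanTruthParams()
window <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day")

writeTagLines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c(paste(c("tag_id", "row_type", "utc", "lat", "lon", "lq",
                       "sst", "sst_time_min",
                       paste0(c("d", "t"), rep(1:6, each = 2)),
                       "dt_time_min"), collapse = ","),
               lines), path)
  path
}

## compose 21-field dialect lines programmatically to keep the arity right
fixLine <- function(utc, lat, lon, lq)
  paste(c("T1", "FIX", utc, lat, lon, lq, rep("", 15)), collapse = ",")
diveLine <- function(dt, pairs)
  paste(c("T1", "DIVE", rep("", 4), "21.0", "40", pairs,
          rep("", 12 - length(pairs)), dt), collapse = ",")
diagLine <- function() paste(c("T1", "DIAG", "BATT=3.6V", rep("", 18)),
                             collapse = ",")

test_that("parsing drops diagnostics, keeps order, flags malformed rows", {
  path <- writeTagLines(c(
    fixLine("2021-06-15T12:00:00", 40.1, 17.1, "0"),
    diveLine(30, c(5, 20.1, 10, 19.9)),
    diagLine(),
    fixLine("2021-06-15T18:00:00", 40.2, 17.2, "3"),
    diveLine(35, c(8, 19.5, 12, 19.0)),
    diagLine()))
  rec <- parseTagFile(path)
  expect_equal(nrow(rec), 4L)
  expect_equal(attr(rec, "n_rows"), 6L)
  expect_equal(attr(rec, "n_diag"), 2L)
  expect_equal(rec$row_type, c("FIX", "DIVE", "FIX", "DIVE"))

  bad <- writeTagLines(diveLine(30, c("five", 20.1)))
  expect_error(parseTagFile(bad), "line 2.*d1")

  empty <- writeTagLines(character(0))
  expect_warning(rec0 <- parseTagFile(empty), "no records")
  expect_equal(nrow(rec0), 0L)
})

test_that("location-quality filtering keeps class 0 and valid fixes only", {
  recs <- bindRecords(
    fixRecord(lq = "3", line = 2L), diveRecord(line = 3L),
    fixRecord(lq = "0", line = 4L), diveRecord(line = 5L),
    fixRecord(lq = "B", line = 6L), diveRecord(line = 7L))
  kept <- filterFixes(recs)
  expect_equal(sum(kept$row_type == "FIX"), 1L)
  expect_equal(kept$lq[kept$row_type == "FIX"], "0")
  fc <- attr(kept, "filter_counts")
  expect_equal(unname(fc["n_fix_lq"]), 2)
  expect_equal(unname(fc["n_dive_rows_lq"]), 2)

  # widening the admitted set retains the precise classes too
  kept2 <- filterFixes(recs, allowed_lq = c("0", "1", "2", "3"))
  expect_equal(sum(kept2$row_type == "FIX"), 2L)

  # a fix lacking coordinates is removed regardless of class
  noLat <- fixRecord(lq = "0", lat = NA_real_)
  kept3 <- filterFixes(bindRecords(noLat, diveRecord()))
  expect_equal(nrow(kept3), 0L)
  expect_equal(unname(attr(kept3, "filter_counts")["n_fix_invalid"]), 1)

  expect_error(filterFixes(recs, allowed_lq = "Q"), "unknown LQ")
})

test_that("filtering is monotone in the admitted class set", {
  tp <- turtleSimParams(n_turtles = 3, n_dives_per_turtle = 30, seed = 8)
  dives <- simulateTurtleDives(tp, truth, window)
  dir <- withr::local_tempdir()
  encodeTagFiles(dives, dir)
  sets <- list("0", c("0", "1"), c("0", "1", "2", "3"),
               c("Z", "B", "A", "0", "1", "2", "3"))
  ns <- vapply(sets, function(s)
    length(decodeTagDirectory(dir, allowed_lq = s)$profiles), 0L)
  expect_true(all(diff(ns) >= 0))
  expect_equal(ns[4], 90L)  # admitting everything keeps every dive
})

test_that("dive segmentation follows lattice contiguity of record ranges", {
  # two 6-pair records, trailers 30 and 60 min: contiguous -> one dive
  g1 <- segmentDives(bindRecords(
    fixRecord(),
    diveRecord(dt_time_min = 30, depths = 10 + 1:6, line = 3L),
    diveRecord(dt_time_min = 60, depths = 20 + 1:6, line = 4L)))
  expect_length(g1, 1L)
  expect_equal(nrow(g1[[1]]$rows), 2L)

  # trailers 30 and 120: a 60-min hole in the lattice -> two dives
  g2 <- segmentDives(bindRecords(
    fixRecord(),
    diveRecord(dt_time_min = 30, depths = 10 + 1:6, line = 3L),
    diveRecord(dt_time_min = 120, depths = 20 + 1:6, line = 4L)))
  expect_length(g2, 2L)

  # a single record forms a single dive group
  g3 <- segmentDives(bindRecords(fixRecord(), diveRecord()))
  expect_length(g3, 1L)

  # dive rows before any fix are dropped, with a warning
  expect_warning(g4 <- segmentDives(bindRecords(diveRecord(), fixRecord(),
                                                diveRecord(line = 4L))),
                 "no preceding FIX")
  expect_length(g4, 1L)
  expect_equal(attr(g4, "n_orphan_dive_rows"), 1L)
})

test_that("retroactive time reconstruction matches the hand-worked example", {
  # fix at 12:00, one record, trailer 30 min, 4 pairs ->
  # samples at 11:15, 11:20, 11:25, 11:30
  g <- segmentDives(bindRecords(
    fixRecord(utc = "2021-06-15T12:00:00"),
    diveRecord(dt_time_min = 30, depths = c(5, 10, 10, 5))))
  res <- reconstructDiveProfile(g[[1]])
  expect_equal(res$status, "ok")
  expect_equal(format(diveSamples(res$profile)$utc, "%H:%M"),
               c("11:15", "11:20", "11:25", "11:30"))
  expect_equal(diveSamples(res$profile)$depth_m, c(5, 10, 10, 5))
})

test_that("temporal-coherence truncation keeps the run ending most recently", {
  # merged sample times (minutes before the fix): -40, -35, -45, -30.
  # The coherent run ending at the most recent sample is -40, -35, -30.
  fix <- fixRecord(utc = "2021-06-15T12:00:00")
  rows <- bindRecords(
    fix,
    diveRecord(dt_time_min = 35, depths = c(1, 2), temps = c(20, 19),
               line = 3L),                      # times -40, -35
    diveRecord(dt_time_min = 45, depths = c(3), temps = c(18), line = 4L),
    diveRecord(dt_time_min = 30, depths = c(4), temps = c(17), line = 5L))
  # force a single group: records overlap, so feed the group directly
  g <- list(fix = fix, rows = rows[rows$row_type == "DIVE", ])
  res <- reconstructDiveProfile(g)
  expect_equal(res$status, "ok")
  mins <- as.numeric(difftime(diveSamples(res$profile)$utc,
                              fix$utc, units = "mins"))
  expect_equal(mins, c(-40, -35, -30))
  expect_equal(diveSamples(res$profile)$depth_m, c(1, 2, 4))
  expect_equal(res$n_truncated, 1L)

  # prefix mode keeps the earliest coherent run instead
  resP <- reconstructDiveProfile(g, truncate = "prefix")
  minsP <- as.numeric(difftime(diveSamples(resP$profile)$utc,
                               fix$utc, units = "mins"))
  expect_equal(minsP, c(-40, -35))

  # duplicate timestamps are incoherent and trigger truncation
  gd <- list(fix = fix,
             rows = rbind(diveRecord(dt_time_min = 30, depths = c(1, 2),
                                     temps = c(20, 19)),
                          diveRecord(dt_time_min = 30, depths = c(3, 4),
                                     temps = c(18, 17), line = 4L)))
  resD <- reconstructDiveProfile(gd)
  expect_equal(resD$status, "ok")
  expect_lt(nrow(diveSamples(resD$profile)), 4L)
})

test_that("surfacing samples are discarded and thin dives rejected", {
  fix <- fixRecord(utc = "2021-06-15T12:00:00")
  g <- list(fix = fix,
            rows = diveRecord(dt_time_min = 30, depths = c(0, 3.2, 7.5, 0),
                              temps = c(18, 19, 20, 21)))
  res <- reconstructDiveProfile(g)
  expect_equal(res$status, "ok")
  expect_equal(diveSamples(res$profile)$depth_m, c(3.2, 7.5))
  expect_equal(res$n_zero_depth, 2L)
  # shallow sub-surface depths (0, 0.5] survive: only exact 0 m is surfacing
  g2 <- list(fix = fix,
             rows = diveRecord(dt_time_min = 30, depths = c(0.3, 3, 7, 0.2),
                               temps = c(18, 19, 20, 21)))
  expect_equal(nrow(diveSamples(reconstructDiveProfile(g2)$profile)), 4L)

  # a dive reduced below two samples lacks a start/end point
  g3 <- list(fix = fix, rows = diveRecord(dt_time_min = 30, depths = c(0, 5),
                                          temps = c(18, 19)))
  res3 <- reconstructDiveProfile(g3)
  expect_equal(res3$status, "rejected")
  expect_equal(res3$reason, "too_few_samples")

  # a populated pair missing its depth or temperature rejects the dive
  g4 <- list(fix = fix,
             rows = diveRecord(dt_time_min = 30, depths = c(5, NA, 15),
                               temps = c(18, 19, 20)))
  expect_equal(reconstructDiveProfile(g4)$reason, "missing_values")

  # a record without its time trailer cannot be reconstructed
  g5 <- list(fix = fix, rows = diveRecord(dt_time_min = NA_real_))
  expect_equal(reconstructDiveProfile(g5)$reason, "missing_time")
})

test_that("decode inverts encode exactly on clean simulated dives", {
  tp <- turtleSimParams(n_turtles = 4, n_dives_per_turtle = 15,
                        lq_probabilities = c(Z = 0, B = 0, A = 0, `0` = 1,
                                             `1` = 0, `2` = 0, `3` = 0),
                        seed = 13)
  dives <- simulateTurtleDives(tp, truth, window)
  dir <- withr::local_tempdir()
  encodeTagFiles(dives, dir)
  dec <- decodeTagDirectory(dir)
  expect_length(dec$profiles, length(dives))
  expect_equal(dec$counts$n_rejected, 0L)

  key <- function(tag, utc) paste(tag, format(utc[1], "%Y%m%d%H%M"))
  simByKey <- stats::setNames(dives, vapply(dives, function(d)
    key(d$tag_id, d$samples$utc), ""))
  for (p in as.list(dec$profiles)) {
    s <- diveSamples(p)
    d <- simByKey[[key(tagId(p), s$utc)]]
    expect_false(is.null(d))
    expect_identical(as.numeric(s$utc), as.numeric(d$samples$utc))
    expect_identical(s$depth_m, d$samples$depth_m)
    expect_identical(s$temp_c, d$samples$temp_c)
    expect_equal(fixLat(p), d$fix_lat)
  }
})

test_that("every loss is accounted for: rows reconcile per file", {
  tp <- turtleSimParams(n_turtles = 5, n_dives_per_turtle = 30, seed = 17)
  dives <- simulateTurtleDives(tp, truth, window)
  dir <- withr::local_tempdir()
  encodeTagFiles(dives, dir)
  dec <- decodeTagDirectory(dir)
  for (cf in dec$per_file) {
    expect_equal(cf$n_candidate_dives, cf$n_profiles + cf$n_rejected)
  }
  c0 <- dec$counts
  expect_equal(c0$n_candidate_dives, c0$n_profiles + c0$n_rejected)
  # all profile samples obey the type invariants
  for (p in as.list(dec$profiles)) expect_true(validObject(p, test = TRUE))
})
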