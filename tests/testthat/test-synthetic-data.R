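truth <- oceanTruthParams()
window <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day")

test_that("truth field honours the logistic thermocline shape", {
  d <- as.Date("2021-08-14")  # day-of-year 226, surface maximum
  lat0 <- truth$lat0

  # saturation: well below the thermocline the field relaxes to t_deep
  expect_equal(truthTemperature(1000, d, lat0, truth), truth$t_deep,
               tolerance = 1e-3 / abs(truth$t_deep))
  # midpoint: at z = MLD(t) the field sits halfway between surface and deep
  mld <- mixedLayerDepth(d, truth)
  expect_equal(truthTemperature(mld, d, lat0, truth),
               (surfaceTemperature(d, truth) + truth$t_deep) / 2)
  # surface saturation with a sharp, deep mixed layer
  sharp <- oceanTruthParams(mld_winter = 50, mld_summer = 50, w_thermo = 2)
  expect_equal(truthTemperature(0, d, lat0, sharp),
               surfaceTemperature(d, sharp), tolerance = 1e-3)

  # continuity and bounds over a depth/date sweep
  zz <- seq(0, 300, by = 0.5)
  tt <- truthTemperature(zz, d, lat0, truth)
  expect_true(all(diff(tt) < 0))  # monotone cooling with depth in summer
  expect_true(all(tt <= surfaceTemperature(d, truth) + 1e-9))
  expect_true(all(tt >= truth$t_deep - 1e-9))

  expect_error(truthTemperature(-1, d, lat0, truth), "non-negative")
})

test_that("seasonal cycle peaks at peak_doy and the mixed layer follows it", {
  peak <- surfaceTemperature(as.Date("2021-08-14"), truth)
  trough <- surfaceTemperature(as.Date("2021-02-12"), truth)
  expect_equal(peak, truth$t_mean + truth$a_surf, tolerance = 1e-4)
  expect_equal(trough, truth$t_mean - truth$a_surf, tolerance = 1e-3)
  expect_equal(mixedLayerDepth(as.Date("2021-08-14"), truth),
               truth$mld_summer, tolerance = 1e-3)
  expect_equal(mixedLayerDepth(as.Date("2021-02-12"), truth),
               truth$mld_winter, tolerance = 0.05)
})

test_that("model product equals truth at grid nodes when unperturbed", {
  bbox <- list(lon_min = 17, lon_max = 17.3, lat_min = 40, lat_max = 40.3)
  prod0 <- modelProductParams(grid_step = 0.1, depth_levels = c(5, 20, 60),
                              bias_profile = 0, noise_sd = 0)
  dates <- as.Date("2021-06-01") + 0:2
  f <- generateModelField(truth, prod0, dates, bbox)
  v <- fieldValues(f)
  for (ti in 1:3) for (zi in 1:3) for (yi in seq_along(fieldLats(f)))
    expect_equal(unique(v[ti, zi, yi, ]),
                 truthTemperature(fieldDepths(f)[zi], dates[ti],
                                  fieldLats(f)[yi], truth))

  # constant bias shifts the field exactly
  prodB <- modelProductParams(grid_step = 0.1, depth_levels = c(5, 20, 60),
                              bias_profile = 0.5, noise_sd = 0)
  fb <- generateModelField(truth, prodB, dates, bbox)
  expect_equal(fieldValues(fb) - v, array(0.5, dim = dim(v)))

  # seeded reproducibility is bit-exact
  prodN <- modelProductParams(grid_step = 0.1, depth_levels = c(5, 20, 60),
                              noise_sd = 0.3, seed = 99)
  expect_identical(fieldValues(generateModelField(truth, prodN, dates, bbox)),
                   fieldValues(generateModelField(truth, prodN, dates, bbox)))

  expect_error(generateModelField(truth, prod0, as.Date(character()), bbox),
               "empty date range")
  expect_error(generateModelField(truth, prod0, dates,
                                  list(lon_min = 17, lon_max = 17,
                                       lat_min = 40, lat_max = 41)),
               "degenerate")
})

test_that("simulated dives respect the tag's physical caps", {
  tp <- turtleSimParams(n_turtles = 10, n_dives_per_turtle = 100, seed = 3)
  dives <- simulateTurtleDives(tp, truth, window)
  expect_length(dives, 1000L)

  maxDepths <- vapply(dives, function(d) max(d$samples$depth_m), 0)
  spans <- vapply(dives, function(d)
    as.numeric(difftime(max(d$samples$utc), min(d$samples$utc),
                        units = "mins")), 0)
  expect_true(all(maxDepths <= 175))
  expect_true(all(spans <= 240 - 5))  # n samples cover duration - 5 minutes
  onLattice <- vapply(dives, function(d) {
    s <- as.numeric(d$samples$utc)
    all(diff(s) == 300) && all(s %% 60 == 0)
  }, TRUE)
  expect_true(all(onLattice))
  expect_true(all(vapply(dives, function(d) all(d$samples$depth_m > 0), TRUE)))

  # exact count example at small n
  small <- simulateTurtleDives(
    turtleSimParams(n_turtles = 2, n_dives_per_turtle = 10, seed = 1),
    truth, window)
  expect_length(small, 20L)

  # determinism under a fixed seed
  again <- simulateTurtleDives(tp, truth, window)
  expect_identical(dives, again)

  expect_error(simulateTurtleDives(
    turtleSimParams(bbox = list(lon_min = 17, lon_max = 16, lat_min = 40,
                                lat_max = 41)), truth, window), "bbox")
})

test_that("tag encoding blocks samples by sixes with per-record trailers", {
  t0 <- as.POSIXct("2021-06-15 11:15:00", tz = "UTC")
  mkDive <- function(n, fixGap = 30) {
    utc <- t0 + 300 * (seq_len(n) - 1)
    list(tag_id = "SYN900", date = as.Date("2021-06-15"),
         true_lat = 40.5, true_lon = 17.5, fix_lat = 40.5, fix_lon = 17.5,
         lq = "0", fix_utc = utc[n] + 60 * fixGap,
         samples = data.frame(utc = utc, depth_m = seq(2, 2 + n - 1),
                              temp_c = 20 + seq_len(n) / 10),
         sst = 21.5, sst_time_min = 99, transmitted = TRUE)
  }
  dir <- withr::local_tempdir()

  # a 20-min dive (4 samples): one DIVE row, 4 pairs, 2 empty slots
  paths <- encodeTagFiles(structure(list(mkDive(4)), class = "simulatedDives"),
                          dir, diag_every = 0L)
  rec <- parseTagFile(paths[[1]])
  dv <- rec[rec$row_type == "DIVE", ]
  expect_equal(nrow(dv), 1L)
  expect_equal(unlist(dv[paste0("d", 1:6)], use.names = FALSE),
               c(2, 3, 4, 5, NA, NA))
  expect_equal(dv$dt_time_min, 30)  # trailer anchors the most recent pair

  # a 60-min dive (12 samples): two rows of six pairs each, most recent first
  paths <- encodeTagFiles(structure(list(mkDive(12)),
                                    class = "simulatedDives"),
                          withr::local_tempdir(), diag_every = 0L)
  rec <- parseTagFile(paths[[1]])
  dv <- rec[rec$row_type == "DIVE", ]
  expect_equal(nrow(dv), 2L)
  expect_false(anyNA(unlist(dv[paste0("d", 1:6)])))
  expect_equal(dv$dt_time_min, c(30, 30 + 6 * 5))
  expect_equal(unlist(dv[1, paste0("d", 1:6)], use.names = FALSE), 8:13)
  expect_equal(unlist(dv[2, paste0("d", 1:6)], use.names = FALSE), 2:7)
})

test_that("argo simulator reproduces truth exactly at zero noise", {
  bbox <- list(lon_min = 17, lon_max = 17.5, lat_min = 40, lat_max = 40.5)
  a0 <- simulateArgoProfiles(3, truth, bbox, window, max_depth = 15,
                             noise_sd = 0, seed = 4)
  expect_equal(length(unique(a0$platform_id)), 3L)
  for (pid in unique(a0$platform_id)) {
    p <- a0[a0$platform_id == pid, ]
    expect_equal(p$temp_c,
                 truthTemperature(p$depth_m, as.Date(p$utc[1]), p$lat[1],
                                  truth))
    expect_equal(p$depth_m, 0:15)
  }
  expect_identical(a0, simulateArgoProfiles(3, truth, bbox, window,
                                            max_depth = 15, noise_sd = 0,
                                            seed = 4))
})
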