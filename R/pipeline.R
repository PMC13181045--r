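## Config-driven pipeline: simulate -> decode -> matchup -> stats ->
## argo-check, with a manifest and reason-coded drop accounting.

defaultConfig <- function() {
  list(
    seed = 1L,
    out_dir = "divetherm-out",
    dates = list(start = "2021-01-01", end = "2021-12-31"),
    paths = list(tags_dir = NULL, field_file = NULL, regions_file = NULL,
                 argo_file = NULL),
    truth = list(t_deep = 13, t_mean = 19, a_surf = 6, peak_doy = 226,
                 mld_winter = 90, mld_summer = 15, w_thermo = 20,
                 lat_gradient = -0.2, lat0 = 41),
    model = list(grid_step = 1 / 24, depth_levels = NULL, bias = 0,
                 bias_step_depth = NULL, bias_step_value = NULL,
                 noise_sd = 0),
    turtles = list(n_turtles = 7, n_dives_per_turtle = 45,
                   bbox = list(lon_min = 16.8, lon_max = 18.4,
                               lat_min = 40.3, lat_max = 41.8),
                   depth_scale = 25, depth_min = 5, depth_max = 175,
                   duration_max = 240, minutes_per_metre = 2.4,
                   sample_interval = 5,
                   lq_probabilities = list(Z = 0.05, B = 0.1, A = 0.1,
                                           `0` = 0.5, `1` = 0.1, `2` = 0.1,
                                           `3` = 0.05),
                   lq0_position_error_sd = 1500, obs_noise_sd = 0,
                   transmission_prob = 1),
    argo = list(n_profiles = 25, max_depth = 40, noise_sd = 0.05),
    analysis = list(allowed_lq = list("0"), truncate = "suffix",
                    max_match_km = 25,
                    depth_breaks = list(0, 15, 30, 50, 100),
                    argo_max_km = 10, argo_max_days = 15, argo_zmax = 12,
                    report_r_min = 0.6, report_p_max = 0.05),
    write_field = FALSE)
}

mergeConfig <- function(defaults, user, path = "") {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(defaults))
      stop("unknown configuration key: ", full, call. = FALSE)
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]])) {
      defaults[[k]] <- mergeConfig(defaults[[k]], user[[k]], full)
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), applies defaults for every
#' missing key, rejects unknown keys (typo guard), and type-checks the
#' numeric parameters. All tag-dialect and analysis constants (5-min
#' sampling, 240-min storage cap, 175 m depth cap, 100 m analysis cap,
#' 10 km / 15 day ARGO thresholds, the admitted LQ set, depth-range edges)
#' are surfaced here so experiments can perturb them.
#'
#' @param config path to a YAML file, or a (possibly partial) config list.
#' @return the completed configuration list, classed `RunConfig`.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config) %||% list()
  }
  stopifnot(is.list(config))
  cfg <- mergeConfig(defaultConfig(), config)
  if (!is.null(cfg$model$noise_sd) && cfg$model$noise_sd < 0)
    stop("configuration error at key model.noise_sd: must be >= 0",
         call. = FALSE)
  if (cfg$model$grid_step <= 0)
    stop("configuration error at key model.grid_step: must be > 0",
         call. = FALSE)
  if (cfg$turtles$depth_max > 175)
    stop("configuration error at key turtles.depth_max: cap is 175 m",
         call. = FALSE)
  if (cfg$turtles$duration_max > 240)
    stop("configuration error at key turtles.duration_max: cap is 240 min",
         call. = FALSE)
  if (cfg$argo$noise_sd < 0)
    stop("configuration error at key argo.noise_sd: must be >= 0",
         call. = FALSE)
  for (p in names(cfg$paths)) {
    if (!is.null(cfg$paths[[p]]) && !file.exists(cfg$paths[[p]]))
      stop("configuration error at key paths.", p, ": file not found: ",
           cfg$paths[[p]], call. = FALSE)
  }
  structure(cfg, class = "RunConfig")
}

configModelParams <- function(cfg) {
  levels <- unlist(cfg$model$depth_levels) %||% defaultDepthLevels()
  bias <- rep_len(unlist(cfg$model$bias), length(levels))
  if (!is.null(cfg$model$bias_step_depth))
    bias <- bias + cfg$model$bias_step_value *
      (levels > cfg$model$bias_step_depth)
  modelProductParams(grid_step = cfg$model$grid_step, depth_levels = levels,
                     bias_profile = bias, noise_sd = cfg$model$noise_sd,
                     seed = deriveSeed(cfg$seed, 2L))
}

configTruthParams <- function(cfg) do.call(oceanTruthParams, cfg$truth)

configTurtleParams <- function(cfg) {
  tp <- cfg$turtles
  turtleSimParams(
    n_turtles = tp$n_turtles, n_dives_per_turtle = tp$n_dives_per_turtle,
    bbox = tp$bbox, depth_scale = tp$depth_scale, depth_min = tp$depth_min,
    depth_max = tp$depth_max, duration_max = tp$duration_max,
    minutes_per_metre = tp$minutes_per_metre,
    sample_interval = tp$sample_interval,
    lq_probabilities = unlist(tp$lq_probabilities),
    lq0_position_error_sd = tp$lq0_position_error_sd,
    obs_noise_sd = tp$obs_noise_sd,
    transmission_prob = tp$transmission_prob,
    seed = deriveSeed(cfg$seed, 1L))
}

#' Run the full synthetic validation pipeline
#'
#' Executes simulate (truth field, model product, turtle tag files, ARGO
#' profiles), decode, matchup, stratified statistics and the ARGO
#' consistency check, writing every stage output plus a JSON manifest
#' (config hash, seed, per-stage row counts and drop reasons) and a run log
#' under `out_dir`. Deterministic stages are bit-identical across reruns of
#' the same configuration.
#'
#' @param config a [validateConfig()] result, a config list, or a YAML path.
#' @param out_dir overrides `config$out_dir` when given.
#' @return invisibly, a list with the stage results (`profiles`, `pairs`,
#'   `summary`, `layers_season`, `layers_subregion`, `argo_bias`,
#'   `manifest`) and the output directory.
#' @export
runPipeline <- function(config = list(), out_dir = NULL) {
  cfg <- if (inherits(config, "RunConfig")) config else validateConfig(config)
  dir <- out_dir %||% cfg$out_dir
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  logFile <- file.path(dir, "run.log")
  logLines <- character(0)
  say <- function(fmt, ...) {
    logLines <<- c(logLines, sprintf(fmt, ...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  dates <- seq(as.Date(cfg$dates$start), as.Date(cfg$dates$end), by = "day")
  truth <- configTruthParams(cfg)
  manifest <- list(seed = cfg$seed, stages = list())

  ## --- simulate -----------------------------------------------------------
  sim <- stage("simulate", {
    tp <- configTurtleParams(cfg)
    dives <- simulateTurtleDives(tp, truth, dates)
    tagsDir <- cfg$paths$tags_dir %||% file.path(dir, "tags")
    if (is.null(cfg$paths$tags_dir)) encodeTagFiles(dives, tagsDir)
    diveDates <- sort(unique(as.Date(vapply(dives, function(d)
      as.character(d$date), ""))))
    fieldDatesUsed <- seq(min(diveDates), max(diveDates), by = "day")
    field <- if (!is.null(cfg$paths$field_file))
      readGriddedField(cfg$paths$field_file)
    else
      generateModelField(truth, configModelParams(cfg), fieldDatesUsed,
                         cfg$turtles$bbox)
    if (isTRUE(cfg$write_field) && is.null(cfg$paths$field_file))
      writeGriddedField(field, file.path(dir, "model_field.csv"))
    argo <- if (!is.null(cfg$paths$argo_file)) {
      a <- data.table::fread(cfg$paths$argo_file, data.table = FALSE)
      a$utc <- parseUtc(as.character(a$utc))
      a
    } else {
      a <- simulateArgoProfiles(cfg$argo$n_profiles, truth,
                                cfg$turtles$bbox, diveDates,
                                max_depth = cfg$argo$max_depth,
                                noise_sd = cfg$argo$noise_sd,
                                seed = deriveSeed(cfg$seed, 3L))
      aw <- a
      aw$utc <- formatUtc(aw$utc)
      data.table::fwrite(aw, file.path(dir, "argo.csv"))
      a
    }
    say("simulate: %d dives, field %d dates x %d levels, %d argo rows",
        length(dives), length(fieldDates(field)),
        length(fieldDepths(field)), nrow(argo))
    list(dives = dives, field = field, argo = argo, tagsDir = tagsDir)
  })
  manifest$stages$simulate <- list(n_dives = length(sim$dives),
                                   n_argo_rows = nrow(sim$argo))

  ## --- decode -------------------------------------------------------------
  dec <- stage("decode", {
    d <- decodeTagDirectory(sim$tagsDir,
                            allowed_lq = unlist(cfg$analysis$allowed_lq),
                            truncate = cfg$analysis$truncate,
                            interval = cfg$turtles$sample_interval)
    writeProfiles(d$profiles, file.path(dir, "profiles.csv"))
    data.table::fwrite(d$rejections, file.path(dir, "rejections.csv"))
    say("decode: %d rows -> %d profiles, %d rejected (%s), lq-filtered dive rows %d",
        d$counts$n_rows, d$counts$n_profiles, d$counts$n_rejected,
        paste(names(table(d$rejections$reason)),
              table(d$rejections$reason), sep = "=", collapse = ","),
        d$counts$n_dive_rows_lq)
    d
  })
  manifest$stages$decode <- dec$counts

  ## --- matchup ------------------------------------------------------------
  pairs <- stage("matchup", {
    regions <- if (!is.null(cfg$paths$regions_file))
      readRegionSet(cfg$paths$regions_file) else defaultRegionSet()
    pr <- collocate(dec$profiles, sim$field, regions,
                    max_match_km = cfg$analysis$max_match_km,
                    depth_breaks = unlist(cfg$analysis$depth_breaks))
    writePairs(pr, file.path(dir, "pairs.csv"))
    um <- attr(pr, "unmatched")
    say("matchup: %d pairs from %d profiles; unmatched: %s", nrow(pr),
        length(dec$profiles),
        if (length(um)) paste(names(um), um, sep = "=", collapse = ",")
        else "none")
    pr
  })
  manifest$stages$matchup <- list(n_pairs = nrow(pairs),
                                  unmatched = as.list(attr(pairs,
                                                           "unmatched")))

  ## --- stats --------------------------------------------------------------
  stats <- stage("stats", {
    su <- stratifiedSummary(pairs, by = c("season", "depth_range"),
                            report_filter = "r_significant",
                            r_min = cfg$analysis$report_r_min,
                            p_max = cfg$analysis$report_p_max)
    data.table::fwrite(su, file.path(dir, "summary_season_depth.csv"))
    ls <- layerProfileSummary(pairs, "season")
    data.table::fwrite(ls, file.path(dir, "layers_season.csv"))
    lr <- layerProfileSummary(pairs, "subregion")
    data.table::fwrite(lr, file.path(dir, "layers_subregion.csv"))
    say("stats: %d strata (%d reported)", nrow(su), sum(su$reported))
    list(summary = su, layers_season = ls, layers_subregion = lr)
  })
  manifest$stages$stats <- list(n_strata = nrow(stats$summary))

  ## --- argo-check ---------------------------------------------------------
  argoBias <- stage("argo-check", {
    turtleDf <- profilesToDataFrame(dec$profiles)
    pairings <- pairArgoTurtle(turtleDf, sim$argo,
                               max_dist_km = cfg$analysis$argo_max_km,
                               max_days = cfg$analysis$argo_max_days,
                               max_depth = cfg$analysis$argo_zmax)
    bb <- binnedBias(pairings, zmax = cfg$analysis$argo_zmax)
    data.table::fwrite(bb, file.path(dir, "argo_bias.csv"))
    say("argo-check: %d pairings over %d bins", nrow(pairings),
        sum(bb$n > 0))
    list(pairings = pairings, bias = bb)
  })
  manifest$stages$argo_check <- list(n_pairings = nrow(argoBias$pairings))

  ## --- manifest -----------------------------------------------------------
  cfgPath <- file.path(dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfgPath)
  manifest$config_hash <- unname(tools::md5sum(cfgPath))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(logLines, logFile)
  invisible(list(out_dir = dir, profiles = dec$profiles,
                 decode_counts = dec$counts, rejections = dec$rejections,
                 pairs = pairs, summary = stats$summary,
                 layers_season = stats$layers_season,
                 layers_subregion = stats$layers_subregion,
                 argo_pairings = argoBias$pairings,
                 argo_bias = argoBias$bias, manifest = manifest))
}
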