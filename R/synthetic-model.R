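## Default vertical levels, patterned on an operational Mediterranean product:
## fine near the surface (< 4 m spacing in the upper 100 m), coarser below.
defaultDepthLevels <- function() {
  c(1.02, 3.17, 5.46, 7.92, 10.54, 13.33, 16.27, 19.37, 22.61, 25.98,
    29.47, 33.06, 36.74, 40.50, 44.33, 48.20, 52.12, 56.07, 60.04, 64.02,
    68.01, 72.00, 76.00, 80.00, 84.00, 88.00, 92.00, 96.00, 100.00,
    110.00, 120.00, 135.00, 150.00, 165.00, 180.00)
}

#' Parameters of the synthetic gridded model product
#'
#' The model product is generated as truth + systematic depth-dependent bias
#' + independent Gaussian noise, on a regular horizontal grid (default 1/24
#' degree, ~4.2 km) with a fixed set of vertical levels.
#'
#' @param grid_step horizontal grid step in degrees (> 0); default 1/24.
#' @param depth_levels vertical levels in metres, strictly increasing.
#' @param bias_profile systematic offset b(z) in degC: a scalar (applied at
#'   every level) or a vector with one value per depth level.
#' @param noise_sd Gaussian noise standard deviation, degC (>= 0).
#' @param seed integer seed for the noise.
#' @return a validated parameter list of class `ModelProductParams`.
#' @export
modelProductParams <- function(grid_step = 1 / 24,
                               depth_levels = defaultDepthLevels(),
                               bias_profile = 0, noise_sd = 0, seed = 1L) {
  stopifnot(grid_step > 0, noise_sd >= 0, length(depth_levels) >= 1)
  if (any(diff(depth_levels) <= 0))
    stop("depth_levels must be strictly increasing", call. = FALSE)
  if (!length(bias_profile) %in% c(1L, length(depth_levels)))
    stop("bias_profile must be scalar or one value per depth level",
         call. = FALSE)
  structure(list(grid_step = grid_step, depth_levels = depth_levels,
                 bias_profile = rep_len(bias_profile, length(depth_levels)),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ModelProductParams")
}

#' Generate the synthetic gridded model product
#'
#' Samples the known-truth field at the product's grid nodes and perturbs it
#' with the product's systematic bias profile and Gaussian noise:
#' `field(t, z, lat, lon) = truth(z, t, lat) + b(z) + eps`,
#' `eps ~ N(0, noise_sd^2)`. Reproducible under the product seed.
#'
#' @param truth an [oceanTruthParams()] list.
#' @param product a [modelProductParams()] list.
#' @param dates `Date` vector of daily slices (non-empty).
#' @param bbox named list/vector with `lon_min`, `lon_max`, `lat_min`,
#'   `lat_max` (non-degenerate).
#' @param mask optional logical `[lat, lon]` sea mask.
#' @return a [GriddedField-class].
#' @export
generateModelField <- function(truth, product, dates, bbox, mask = NULL) {
  dates <- as.Date(dates)
  if (length(dates) < 1L) stop("empty date range", call. = FALSE)
  bbox <- as.list(bbox)
  if (bbox$lon_max <= bbox$lon_min || bbox$lat_max <= bbox$lat_min)
    stop("degenerate bounding box", call. = FALSE)
  step <- product$grid_step
  lons <- seq(bbox$lon_min + step / 2, bbox$lon_max, by = step)
  lats <- seq(bbox$lat_min + step / 2, bbox$lat_max, by = step)
  nz <- length(product$depth_levels)
  dims <- c(length(dates), nz, length(lats), length(lons))

  values <- array(NA_real_, dim = dims)
  ## truth is zonally uniform: compute one [depth, lat] slab per date,
  ## replicate across longitude.
  for (ti in seq_along(dates)) {
    slab <- outer(product$depth_levels, lats, function(z, la)
      truthTemperature(z, dates[ti], la, truth))
    slab <- slab + product$bias_profile
    values[ti, , , ] <- slab  # recycled over the lon dimension
  }
  if (product$noise_sd > 0) {
    noise <- withr::with_seed(product$seed,
      stats::rnorm(prod(dims), sd = product$noise_sd))
    values <- values + array(noise, dim = dims)
  }
  if (!is.null(mask)) {
    land <- which(!mask, arr.ind = TRUE)
    for (k in seq_len(nrow(land)))
      values[, , land[k, 1], land[k, 2]] <- NA_real_
  }
  griddedField(dates, product$depth_levels, lats, lons, values, mask = mask)
}
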