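#' Pair turtle samples with ARGO samples in space, time and depth
#'
#' Forms all cross pairs of decoded turtle samples and ARGO-style float
#' samples that lie within `max_dist_km` great-circle kilometres of each
#' other (inclusive), were acquired within `max_days` days (inclusive), and
#' fall into the same 1-m depth bin `(k-1, k]`. One turtle sample may pair
#' with several ARGO samples; multiplicity is not restricted.
#'
#' @param turtle samples `data.frame` (from [profilesToDataFrame()] /
#'   [readProfiles()]): `utc`, `lat`, `lon`, `depth_m`, `temp_c`.
#' @param argo ARGO table: `platform_id`, `utc`, `lat`, `lon`, `depth_m`,
#'   `temp_c`.
#' @param max_dist_km separation threshold, km.
#' @param max_days acquisition-time threshold, days.
#' @param max_depth only samples at or above this depth participate, m.
#' @return `data.frame` of pairings: turtle fields (`turtle_*`), argo fields
#'   (`argo_*`, incl. `platform_id`), `separation_km`, `separation_days`,
#'   `depth_bin` (upper edge of the shared 1-m bin).
#' @export
pairArgoTurtle <- function(turtle, argo, max_dist_km = 10, max_days = 15,
                           max_depth = 12) {
  if (nrow(turtle) == 0L || nrow(argo) == 0L)
    stop("both turtle and argo inputs must be non-empty", call. = FALSE)
  tu <- turtle[turtle$depth_m > 0 & turtle$depth_m <= max_depth, ,
               drop = FALSE]
  ar <- argo[argo$depth_m > 0 & argo$depth_m <= max_depth, , drop = FALSE]
  tu$bin <- ceiling(tu$depth_m)
  ar$bin <- ceiling(ar$depth_m)
  out <- list()
  for (b in intersect(unique(tu$bin), unique(ar$bin))) {
    ti <- which(tu$bin == b)
    ai <- which(ar$bin == b)
    grid <- expand.grid(t = ti, a = ai, KEEP.OUT.ATTRS = FALSE)
    sepKm <- haversineKm(tu$lon[grid$t], tu$lat[grid$t],
                         ar$lon[grid$a], ar$lat[grid$a])
    sepDays <- abs(as.numeric(difftime(tu$utc[grid$t], ar$utc[grid$a],
                                       units = "days")))
    keep <- sepKm <= max_dist_km & sepDays <= max_days
    if (!any(keep)) next
    grid <- grid[keep, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      turtle_utc = tu$utc[grid$t], turtle_lat = tu$lat[grid$t],
      turtle_lon = tu$lon[grid$t], turtle_depth_m = tu$depth_m[grid$t],
      turtle_temp_c = tu$temp_c[grid$t],
      argo_platform_id = ar$platform_id[grid$a], argo_utc = ar$utc[grid$a],
      argo_lat = ar$lat[grid$a], argo_lon = ar$lon[grid$a],
      argo_depth_m = ar$depth_m[grid$a], argo_temp_c = ar$temp_c[grid$a],
      separation_km = sepKm[keep], separation_days = sepDays[keep],
      depth_bin = b, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(turtle_utc = as.POSIXct(character(), tz = "UTC"),
                      turtle_lat = numeric(), turtle_lon = numeric(),
                      turtle_depth_m = numeric(), turtle_temp_c = numeric(),
                      argo_platform_id = character(),
                      argo_utc = as.POSIXct(character(), tz = "UTC"),
                      argo_lat = numeric(), argo_lon = numeric(),
                      argo_depth_m = numeric(), argo_temp_c = numeric(),
                      separation_km = numeric(), separation_days = numeric(),
                      depth_bin = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-depth-bin BIAS between ARGO and turtle samples
#'
#' BIAS (oriented ARGO minus turtle by default) and pair count at `dz`-metre
#' vertical bins from the surface to `zmax`. Empty bins are reported with
#' `n = 0` and `NA` BIAS.
#'
#' @param pairings result of [pairArgoTurtle()].
#' @param dz bin width, m.
#' @param zmax deepest bin edge, m.
#' @param orientation `"argo_minus_turtle"` (default) or
#'   `"turtle_minus_argo"`.
#' @return `data.frame` with `depth_bin` (upper edge), `n`, `bias`.
#' @export
binnedBias <- function(pairings, dz = 1, zmax = 12,
                       orientation = c("argo_minus_turtle",
                                       "turtle_minus_argo")) {
  orientation <- match.arg(orientation)
  edges <- seq(dz, zmax, by = dz)
  diff <- pairings$argo_temp_c - pairings$turtle_temp_c
  if (orientation == "turtle_minus_argo") diff <- -diff
  bin <- dz * ceiling(pairings$turtle_depth_m / dz)
  out <- data.frame(depth_bin = edges, n = 0L, bias = NA_real_)
  for (i in seq_along(edges)) {
    sel <- bin == edges[i]
    out$n[i] <- sum(sel)
    if (any(sel)) out$bias[i] <- mean(diff[sel])
  }
  out
}
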