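#' Parameters of the known-truth ocean temperature field
#'
#' The synthetic truth is a seasonally forced logistic thermocline: surface
#' temperature follows an annual cosine, the mixed layer deepens in winter and
#' shoals in summer, and temperature relaxes to an abyssal value below the
#' thermocline. An optional meridional gradient adds horizontal structure.
#' Defaults describe a mid-latitude semi-enclosed basin with strong summer
#' stratification and near-complete winter overturning (surface ~13 degC in
#' winter, ~25 degC in late summer, deep water ~13 degC).
#'
#' @param t_deep abyssal temperature, degC.
#' @param t_mean annual-mean surface temperature, degC.
#' @param a_surf seasonal surface amplitude, degC.
#' @param peak_doy day-of-year of the surface temperature maximum.
#' @param mld_winter,mld_summer mixed-layer depth extremes, m (both > 0).
#' @param w_thermo thermocline half-width, m (> 0).
#' @param lat_gradient surface gradient, degC per degree latitude.
#' @param lat0 reference latitude for the gradient, degrees.
#' @return a validated parameter list of class `OceanTruthParams`.
#' @export
oceanTruthParams <- function(t_deep = 13, t_mean = 19, a_surf = 6,
                             peak_doy = 226, mld_winter = 90, mld_summer = 15,
                             w_thermo = 20, lat_gradient = -0.2, lat0 = 41) {
  stopifnot(w_thermo > 0, mld_winter > 0, mld_summer > 0, a_surf >= 0)
  structure(list(t_deep = t_deep, t_mean = t_mean, a_surf = a_surf,
                 peak_doy = peak_doy, mld_winter = mld_winter,
                 mld_summer = mld_summer, w_thermo = w_thermo,
                 lat_gradient = lat_gradient, lat0 = lat0),
            class = "OceanTruthParams")
}

dayOfYear <- function(date) as.POSIXlt(as.Date(date))$yday + 1

## Annual phase shared by the surface forcing and the mixed-layer cycle.
seasonalCosine <- function(date, peak_doy) {
  cos(2 * pi * (dayOfYear(date) - peak_doy) / 365.25)
}

#' Surface temperature and mixed-layer depth of the truth field
#'
#' @param date calendar date(s) (UTC civil dates).
#' @param lat latitude(s), degrees (surface temperature only).
#' @param params an [oceanTruthParams()] list.
#' @return temperature in degC / depth in m.
#' @export
surfaceTemperature <- function(date, params, lat = params$lat0) {
  params$t_mean + params$a_surf * seasonalCosine(date, params$peak_doy) +
    params$lat_gradient * (lat - params$lat0)
}

#' @rdname surfaceTemperature
#' @export
mixedLayerDepth <- function(date, params) {
  mid <- (params$mld_winter + params$mld_summer) / 2
  amp <- (params$mld_winter - params$mld_summer) / 2
  mid - amp * seasonalCosine(date, params$peak_doy)
}

#' Evaluate the known-truth temperature field
#'
#' `T(z, t, lat) = T_deep + (T_surf(t, lat) - T_deep) * s(z)` with the
#' logistic shape `s(z) = 1 / (1 + exp((z - MLD(t)) / w))`: uniform in the
#' mixed layer, relaxing to `t_deep` across a thermocline of half-width
#' `w_thermo` centred at the seasonally varying mixed-layer depth.
#'
#' @param depth depth(s) in metres, >= 0.
#' @param date calendar date(s).
#' @param lat latitude(s), degrees.
#' @param params an [oceanTruthParams()] list.
#' @return temperature(s) in degC, vectorised over the inputs (recycled).
#' @export
truthTemperature <- function(depth, date, lat, params) {
  depth <- as.numeric(depth)
  if (anyNA(depth) || any(depth < 0))
    stop("depth must be non-negative", call. = FALSE)
  tsurf <- surfaceTemperature(date, params, lat)
  mld <- mixedLayerDepth(date, params)
  s <- 1 / (1 + exp((depth - mld) / params$w_thermo))
  params$t_deep + (tsurf - params$t_deep) * s
}
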