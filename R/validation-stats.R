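#' Pearson correlation with a t-based significance test
#'
#' `r = cov(x, y) / (sd(x) sd(y))` (sample normalisation; the ratio is
#' normalisation-invariant), with a two-sided p-value from the
#' transformation `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length (>= 3), non-zero variance.
#' @return `list(r, p, n)`.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  mx <- sum(x) / n
  my <- sum(y) / n
  covxy <- sum((x - mx) * (y - my)) / (n - 1)
  sx <- sqrt(sum((x - mx)^2) / (n - 1))
  sy <- sqrt(sum((y - my)^2) / (n - 1))
  if (sx == 0 || sy == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  r <- covxy / (sx * sy)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.xmin))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Mean model-minus-observation temperature difference
#'
#' Positive values mean the model is warmer than the observations.
#'
#' @param obs observed temperatures, degC.
#' @param model modelled temperatures, degC (same length).
#' @return BIAS in degC.
#' @export
temperatureBias <- function(obs, model) {
  if (length(obs) == 0L || length(obs) != length(model))
    stop("obs and model must be non-empty and of equal length", call. = FALSE)
  sum(model - obs) / length(obs)
}

#' BIAS, RMSE and unbiased RMSE of a model-observation comparison
#'
#' `RMSE = sqrt(mean((model - obs)^2))`;
#' `uRMSE = sqrt(RMSE^2 - BIAS^2)` (clamped at zero against floating-point
#' negatives) quantifies the residual error after removing the systematic
#' offset.
#'
#' @inheritParams temperatureBias
#' @return `list(bias, rmse, urmse)` in degC.
#' @export
errorMetrics <- function(obs, model) {
  bias <- temperatureBias(obs, model)
  rmse <- sqrt(sum((model - obs)^2) / length(obs))
  urmse <- sqrt(max(rmse^2 - bias^2, 0))
  list(bias = bias, rmse = rmse, urmse = urmse)
}

#' Stratified validation summary
#'
#' One row per occupied stratum (combinations of the requested strata
#' columns) with pair and raw-observation counts, Pearson r and p, BIAS,
#' RMSE and uRMSE. Strata with fewer than 3 pairs (or degenerate variance)
#' report `NA` for the statistics, never silently dropped rows. With
#' `report_filter = "r_significant"`, a logical `reported` column marks the
#' rows an r-filtered report would retain (r above the threshold and p below
#' the significance level); suppressed rows stay in the returned table.
#'
#' @param pairs matched pairs from [collocate()] (or any data.frame with
#'   `obs_temp`, `model_temp` and the strata columns).
#' @param by strata column names, e.g. `c("season", "depth_range")`. Pairs
#'   with `NA` in a stratum column (e.g. levels below the 100 m analysis
#'   cap) are excluded.
#' @param report_filter `NULL` or `"r_significant"`.
#' @param r_min,p_max thresholds for the report filter.
#' @return `data.frame`: strata columns, `n_pairs`, `n_obs`, `r`, `p`,
#'   `bias`, `rmse`, `urmse` (and `reported` when filtered).
#' @export
stratifiedSummary <- function(pairs, by = c("season", "depth_range"),
                              report_filter = NULL, r_min = 0.6,
                              p_max = 0.05) {
  stopifnot(all(by %in% names(pairs)))
  keep <- rowSums(is.na(pairs[, by, drop = FALSE])) == 0
  d <- pairs[keep, , drop = FALSE]
  d <- orderStrata(d, by)
  key <- interaction(d[, by, drop = FALSE], drop = TRUE, lex.order = TRUE)
  out <- lapply(split(d, key), function(g) {
    row <- g[1L, by, drop = FALSE]
    row$n_pairs <- nrow(g)
    row$n_obs <- if ("n_obs" %in% names(g)) sum(g$n_obs) else nrow(g)
    stats <- tryCatch(pearsonR(g$obs_temp, g$model_temp),
                      error = function(e) list(r = NA_real_, p = NA_real_))
    row$r <- stats$r
    row$p <- stats$p
    if (nrow(g) >= 1L) {
      em <- errorMetrics(g$obs_temp, g$model_temp)
      row$bias <- em$bias
      row$rmse <- em$rmse
      row$urmse <- em$urmse
    } else {
      row$bias <- row$rmse <- row$urmse <- NA_real_
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!is.null(report_filter)) {
    report_filter <- match.arg(report_filter, "r_significant")
    out$reported <- !is.na(out$r) & out$r > r_min & !is.na(out$p) &
      out$p < p_max
  }
  out
}

## order strata columns by their natural factor levels where known
orderStrata <- function(d, by) {
  keyCols <- lapply(by, function(b) {
    v <- d[[b]]
    if (b == "season") factor(v, levels = seasonLevels())
    else if (b == "depth_range") factor(v, levels = unique(v[order(
      as.numeric(sub("-.*", "", v)))]))
    else factor(v)
  })
  d[do.call(order, keyCols), , drop = FALSE]
}

#' Per-level mean profile summary
#'
#' Averages matched pairs over a grouping stratum at each model depth level:
#' mean observed and modelled temperature, BIAS and uRMSE per
#' (group, level). Levels with no pairs in a group are omitted.
#'
#' @param pairs matched pairs from [collocate()].
#' @param group one stratum column, typically `"season"` or `"subregion"`.
#' @return `data.frame` with columns `group` value, `depth_level`, `n`,
#'   `mean_obs`, `mean_model`, `bias`, `urmse`.
#' @export
layerProfileSummary <- function(pairs, group = "season") {
  stopifnot(group %in% names(pairs))
  d <- pairs[!is.na(pairs[[group]]), , drop = FALSE]
  key <- interaction(d[[group]], d$depth_level, drop = TRUE, lex.order = TRUE)
  out <- lapply(split(d, key), function(g) {
    em <- errorMetrics(g$obs_temp, g$model_temp)
    df <- data.frame(g[1L, group, drop = FALSE],
                     depth_level = g$depth_level[1L], n = nrow(g),
                     mean_obs = mean(g$obs_temp),
                     mean_model = mean(g$model_temp),
                     bias = em$bias, urmse = em$urmse,
                     stringsAsFactors = FALSE)
    df
  })
  out <- do.call(rbind, out)
  out <- out[order(out[[group]], out$depth_level), , drop = FALSE]
  rownames(out) <- NULL
  out
}
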