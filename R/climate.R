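# Delta-change ("simple pattern") downscaling of coarse climate-model
# anomalies onto a fine baseline climatology, bioclimatic variables, and the
# temporal update schedule for suitability maps.

#' Coarse climate anomaly between a future and a reference field
#'
#' Temperature anomalies are additive differences (future minus reference);
#' precipitation anomalies are multiplicative ratios future/reference with
#' the reference floored at 0.1 mm so near-zero months cannot blow up the
#' ratio.
#'
#' @param gcm_future_month,gcm_reference_month [pva_raster] fields on the
#'   same coarse grid.
#' @param variable_kind `"temperature"` or `"precipitation"`.
#' @return a [pva_raster] anomaly field (difference or ratio).
#' @export
compute_anomaly <- function(gcm_future_month, gcm_reference_month,
                            variable_kind = c("temperature", "precipitation")) {
  variable_kind <- match.arg(variable_kind)
  stop_unless_same_grid(gcm_future_month, gcm_reference_month, "GCM fields")
  vals <- if (variable_kind == "temperature") {
    gcm_future_month$values - gcm_reference_month$values
  } else {
    gcm_future_month$values / pmax(gcm_reference_month$values, 0.1)
  }
  pva_raster(vals, gcm_future_month$cell_size_km, gcm_future_month$origin)
}

#' Downscale a coarse anomaly onto a fine baseline
#'
#' Each fine cell receives the anomaly of its containing coarse cell:
#' baseline + anomaly for temperature, baseline x ratio for precipitation
#' (floored at 0). The coarse grid must be an integer aggregation of the
#' fine grid.
#'
#' @param anomaly_coarse coarse [pva_raster] from [compute_anomaly()].
#' @param baseline_fine fine-resolution baseline [pva_raster].
#' @param variable_kind `"temperature"` or `"precipitation"`.
#' @return fine-resolution [pva_raster].
#' @export
downscale <- function(anomaly_coarse, baseline_fine,
                      variable_kind = c("temperature", "precipitation")) {
  variable_kind <- match.arg(variable_kind)
  anom <- disaggregate_raster(anomaly_coarse, baseline_fine)
  vals <- if (variable_kind == "temperature") {
    baseline_fine$values + anom$values
  } else {
    pmax(baseline_fine$values * anom$values, 0)
  }
  pva_raster(vals, baseline_fine$cell_size_km, baseline_fine$origin,
             label = baseline_fine$label)
}

#' Bioclimatic variables from monthly temperature and precipitation
#'
#' Standard definitions on monthly means: `bio1` annual mean temperature,
#' `bio4` temperature seasonality (standard deviation of monthly means x
#' 100), `bio5` maximum temperature of the warmest month (here the warmest
#' monthly mean), `bio12` annual precipitation, `bio13`/`bio14`
#' precipitation of the wettest/driest month.
#'
#' @param temp_months,prec_months lists of 12 monthly [pva_raster] layers.
#' @param variables subset of
#'   `c("bio1","bio4","bio5","bio12","bio13","bio14")`.
#' @return named list of [pva_raster] layers.
#' @export
derive_bioclim <- function(temp_months, prec_months,
                           variables = c("bio1", "bio4", "bio5",
                                         "bio12", "bio13", "bio14")) {
  if (length(temp_months) != 12 || length(prec_months) != 12)
    stop("derive_bioclim(): need 12 monthly layers for each variable")
  variables <- match.arg(variables, several.ok = TRUE)
  template <- temp_months[[1]]
  tarr <- simplify2array(lapply(temp_months, function(r) r$values))
  parr <- simplify2array(lapply(prec_months, function(r) r$values))
  mk <- function(v) pva_raster(v, template$cell_size_km, template$origin)
  out <- list()
  for (v in variables) {
    out[[v]] <- switch(v,
      bio1 = mk(apply(tarr, c(1, 2), mean)),
      bio4 = mk(apply(tarr, c(1, 2), stats::sd) * 100),
      bio5 = mk(apply(tarr, c(1, 2), max)),
      bio12 = mk(apply(parr, c(1, 2), sum)),
      bio13 = mk(apply(parr, c(1, 2), max)),
      bio14 = mk(apply(parr, c(1, 2), min)))
  }
  out
}

#' Temporal schedule of suitability maps for the simulation
#'
#' Habitat changes slower than the yearly climate signal, so the simulator
#' updates its suitability map only every `update_every` years, each update
#' being the per-cell running mean of the yearly maps over a trailing
#' `window`-year window ending at the update year. Maps are piecewise
#' constant between updates.
#'
#' @param yearly_maps list of [pva_raster] maps on one grid.
#' @param years integer vector of calendar years, parallel to `yearly_maps`.
#' @param start_year first simulation year (update 0 happens here).
#' @param horizon simulation length in years.
#' @param window running-mean window length (>= 1), default 10.
#' @param update_every update interval in years (>= 1), default 5.
#' @return list with `update_years`, `maps` (one averaged map per update),
#'   and `year_index` (for each simulation year 0..horizon, the index of the
#'   scheduled map in force).
#' @export
temporal_schedule <- function(yearly_maps, years, start_year, horizon,
                              window = 10, update_every = 5) {
  if (window < 1 || update_every < 1)
    stop("temporal_schedule(): window and update_every must be >= 1")
  stopifnot(length(yearly_maps) == length(years))
  update_years <- seq(start_year, start_year + horizon, by = update_every)
  maps <- vector("list", length(update_years))
  for (i in seq_along(update_years)) {
    need <- (update_years[i] - window + 1):update_years[i]
    idx <- match(need, years)
    if (any(is.na(idx)))
      stop("temporal_schedule(): yearly map series too short for the window ",
           "ending in ", update_years[i])
    acc <- yearly_maps[[idx[1]]]$values
    for (j in idx[-1]) acc <- acc + yearly_maps[[j]]$values
    maps[[i]] <- pva_raster(acc / window, yearly_maps[[1]]$cell_size_km,
                            yearly_maps[[1]]$origin,
                            label = paste0(update_years[i], "s"))
  }
  sim_years <- start_year + 0:horizon
  year_index <- findInterval(sim_years, update_years)
  list(update_years = update_years, maps = maps, year_index = year_index)
}
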