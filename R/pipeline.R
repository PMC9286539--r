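# End-to-end orchestration: synthesize inputs -> SDM ensemble -> climate
# schedule -> patches -> scenario simulations -> comparison, from a single
# YAML configuration, with a provenance manifest.

REQUIRED_CONFIG_FIELDS <- c(
  "seed", "landscape.rows", "landscape.cols",
  "occurrences.n_presence", "occurrences.n_background",
  "landcover.fraction_unsuitable",
  "patches.suitability_threshold", "patches.neighborhood_km", "patches.density",
  "simulation.n_replicates", "simulation.horizon_years", "scenarios")

config_get <- function(config, path) {
  node <- config
  for (key in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (!is.list(node) || is.null(node[[key]])) return(NULL)
    node <- node[[key]]
  }
  node
}

#' Validate a pipeline configuration
#'
#' Checks the presence of every required field and basic value sanity;
#' violations are reported with their field paths before any computation.
#'
#' @param config named list, typically parsed from YAML.
#' @return `config`, invisibly, on success.
#' @export
validate_config <- function(config) {
  missing <- REQUIRED_CONFIG_FIELDS[vapply(REQUIRED_CONFIG_FIELDS, function(p)
    is.null(config_get(config, p)), logical(1))]
  if (length(missing) > 0)
    stop("invalid config: missing field(s): ", paste(missing, collapse = ", "))
  bad <- character(0)
  if (config_get(config, "simulation.n_replicates") < 1)
    bad <- c(bad, "simulation.n_replicates (must be >= 1)")
  if (config_get(config, "simulation.horizon_years") < 1)
    bad <- c(bad, "simulation.horizon_years (must be >= 1)")
  f <- config_get(config, "landcover.fraction_unsuitable")
  if (f < 0 || f > 1) bad <- c(bad, "landcover.fraction_unsuitable (must be in [0, 1])")
  if (length(bad) > 0) stop("invalid config: ", paste(bad, collapse = "; "))
  invisible(config)
}

# default plant-like stage matrix used when the config supplies none:
# high stasis, slow maturation, adult-dominated reproduction, lambda near 1
default_truth_matrix <- function() {
  leslie_matrix(rbind(
    c(0.45, 0.05, 0.95),
    c(0.25, 0.70, 0.00),
    c(0.00, 0.20, 0.80)))
}

# monthly baseline climatology synthesized from the landscape predictors:
# a seasonal cycle around bio1 and a seasonal split of bio12
baseline_monthly_climate <- function(landscape) {
  bio1 <- landscape$predictors$bio1
  bio12 <- landscape$predictors$bio12
  months <- 1:12
  temp <- lapply(months, function(m)
    pva_raster(bio1$values + 6 * cos(2 * pi * (m - 1) / 12),
               bio1$cell_size_km, bio1$origin))
  prec <- lapply(months, function(m)
    pva_raster(pmax(bio12$values / 12 * (1 + 0.5 * cos(2 * pi * (m - 1) / 12)), 0),
               bio12$cell_size_km, bio12$origin))
  list(temp = temp, prec = prec)
}

# predict the weighted ensemble suitability for one predictor stack
ensemble_predict <- function(models, weights, predictor_layers, label = NULL) {
  maps <- lapply(models, predict_map, predictor_layers = predictor_layers,
                 label = label)
  ensemble_weighted_mean(maps, weights)
}

#' Run the full coupled analysis from a configuration
#'
#' Executes the stages in dependency order: synthetic landscape, occurrence
#' and land-cover generation; SDM fitting with fivefold evaluation and
#' AUC-weighted ensembling; delta-change climate forcing and yearly
#' suitability projection; the 5-yearly suitability schedule; patch
#' delineation and carrying-capacity schedules; replicated stochastic
#' simulation of every configured scenario (paired seeds across scenarios);
#' and scenario comparison. All randomness flows from the single root seed
#' through named substreams per stage.
#'
#' @param config_path path to a YAML configuration, or a config list.
#' @param out_dir optional output directory; when given, metrics, patch
#'   tables, per-scenario summaries, key rasters and a provenance manifest
#'   (`manifest.json`, with MD5 hashes of every written file) are written
#'   there.
#' @return invisibly, a list with `landscape`, `sdm` (metrics, weights),
#'   `suitability` (initial masked ensemble map), `patches`, `populations`,
#'   `results` (named list of `pva_sim_result`), `summaries`, `comparison`,
#'   and `manifest`.
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  t0 <- Sys.time()
  config <- if (is.character(config_path)) yaml::read_yaml(config_path) else config_path
  validate_config(config)
  seed <- config$seed

  # --- synthetic inputs -----------------------------------------------------
  land <- gen_landscape(
    rows = config$landscape$rows, cols = config$landscape$cols,
    cell_size_km = config$landscape$cell_size_km %||% 1,
    gradient = config$landscape$gradient %||% "linear",
    seed = derive_seed(seed, "landscape"))
  occ <- gen_occurrences(land, config$occurrences$n_presence,
                         config$occurrences$n_background,
                         seed = derive_seed(seed, "occurrences"))
  mask0 <- gen_landcover_mask(land, config$landcover$fraction_unsuitable,
                              clustering = isTRUE(config$landcover$clustering),
                              seed = derive_seed(seed, "landcover"))

  # --- SDM ensemble ---------------------------------------------------------
  algorithms <- unlist(config$sdm$algorithms %||%
                         list("glm", "maxent_like", "random_forest"))
  kk <- config$sdm$k %||% 5
  metrics <- do.call(rbind, lapply(algorithms, function(a)
    kfold_evaluate(occ, land$predictors, a, k = kk,
                   seed = derive_seed(seed, "folds", a))))
  weights <- vapply(algorithms, function(a)
    mean(metrics$auc[metrics$algorithm == a]), numeric(1))
  models <- lapply(algorithms, function(a)
    fit_sdm(occ, land$predictors, a, seed = derive_seed(seed, "fit", a)))
  base_map <- ensemble_predict(models, weights, land$predictors, label = "baseline")
  suit0 <- apply_landcover_mask(base_map, mask0)

  # --- climate forcing and yearly suitability -------------------------------
  horizon <- config$simulation$horizon_years
  window <- config$climate$window %||% 10
  update_every <- config$climate$update_every %||% 5
  start_year <- window - 1      # sim year 0 sits at the end of the first window
  n_clim_years <- start_year + horizon
  baseclim <- baseline_monthly_climate(land)
  gcm <- gen_gcm_series(
    baseclim$temp, baseclim$prec,
    trend_temp_per_year = config$climate$trend_temp_per_year %||% 0.04,
    trend_prec_frac_per_year = config$climate$trend_prec_frac_per_year %||% -0.002,
    n_years = n_clim_years,
    coarse_factor = config$climate$coarse_factor %||% 1,
    noise_sd_temp = config$climate$noise_sd_temp %||% 0.2,
    noise_cv_prec = config$climate$noise_cv_prec %||% 0.05,
    seed = derive_seed(seed, "gcm"))
  yearly_cc_maps <- vector("list", n_clim_years + 1)
  for (i in seq_len(n_clim_years + 1)) {
    temp_fine <- vector("list", 12); prec_fine <- vector("list", 12)
    for (m in 1:12) {
      ta <- compute_anomaly(gcm$temp[[i]][[m]], gcm$temp[[1]][[m]], "temperature")
      pa <- compute_anomaly(gcm$prec[[i]][[m]], gcm$prec[[1]][[m]], "precipitation")
      temp_fine[[m]] <- downscale(ta, baseclim$temp[[m]], "temperature")
      prec_fine[[m]] <- downscale(pa, baseclim$prec[[m]], "precipitation")
    }
    bio <- derive_bioclim(temp_fine, prec_fine, c("bio1", "bio12"))
    yearly_cc_maps[[i]] <- ensemble_predict(models, weights, bio)
  }
  clim_years <- 0:n_clim_years
  schedule_cc <- temporal_schedule(yearly_cc_maps, clim_years, start_year,
                                   horizon, window, update_every)
  schedule_flat <- list(update_years = schedule_cc$update_years,
                        maps = rep(list(base_map), length(schedule_cc$maps)),
                        year_index = schedule_cc$year_index)

  # --- demography -----------------------------------------------------------
  truth_mat <- if (!is.null(config$demography$matrix))
    leslie_matrix(do.call(rbind, config$demography$matrix)) else default_truth_matrix()
  truth <- demography_truth(
    truth_mat, years = config$demography$years %||% 12,
    initial_counts = unlist(config$demography$initial_counts %||% list(600, 300, 300)),
    observation_noise_cv = config$demography$observation_noise_cv %||% 0.05)
  counts <- gen_stage_counts(truth, seed = derive_seed(seed, "census"))
  pool <- build_matrix_pool(counts, config$demography$n_resamples %||% 100,
                            seed = derive_seed(seed, "pool"))
  mats <- select_percentile_matrices(pool)
  A <- mats[["p50"]]
  ssd <- stable_stage_distribution(A)

  # --- patches and carrying-capacity schedules ------------------------------
  thr <- config$patches$suitability_threshold
  density <- config$patches$density
  patches <- delineate_patches(suit0, thr, config$patches$neighborhood_km)
  if (length(patches) == 0) stop("run_pipeline(): no habitat patches at the configured threshold")
  cell_area <- suit0$cell_size_km^2
  pops <- lapply(patches, initialize_population,
                 density_per_suitability_unit = density,
                 stage_distribution = ssd, cell_area_km2 = cell_area)

  k_schedule_for <- function(schedule, mask_series) {
    upd <- schedule$update_years - start_year      # sim years 0, 5, ...
    keep <- upd > 0
    Kmat <- matrix(0, sum(keep), length(patches))
    r <- 0
    for (i in which(keep)) {
      r <- r + 1
      m <- apply_landcover_mask(schedule$maps[[i]], mask_series[[upd[i] + 1]])
      for (p in seq_along(patches))
        Kmat[r, p] <- round(density * sum(m$values[patches[[p]]$cell_index]) * cell_area)
    }
    list(years = upd[keep], K = Kmat)
  }

  # --- scenarios ------------------------------------------------------------
  lcc_spec <- list(kind = "expansion",
                   rate = config$landcover_expansion$rate %||% 0.01,
                   adjacency_radius = config$landcover_expansion$adjacency_radius %||% 1,
                   seed = derive_seed(seed, "expansion"))
  mask_flat <- build_mask_series(mask0, list(kind = "intensification"), horizon)
  mask_exp <- build_mask_series(mask0, lcc_spec, horizon)
  hv_defaults <- config$harvest %||% list()
  results <- list(); summaries <- list()
  sim_seed <- derive_seed(seed, "simulate")   # paired across scenarios
  for (sc_name in names(config$scenarios)) {
    sc <- config$scenarios[[sc_name]]
    schedule <- if (isTRUE(sc$climate)) schedule_cc else schedule_flat
    masks <- if (identical(sc$landcover, "expansion")) mask_exp else mask_flat
    hv <- harvest_spec(sc$harvest %||% "NONE",
                       quota = hv_defaults$quota %||% 5,
                       interval = hv_defaults$interval %||% 2,
                       min_population = hv_defaults$min_population %||% 50)
    cfg <- sim_config(
      A, stochasticity = stochasticity_spec(), harvest = hv,
      n_replicates = config$simulation$n_replicates,
      horizon_years = horizon,
      k_schedule = k_schedule_for(schedule, masks),
      quasi_extinction_threshold = config$simulation$quasi_extinction_threshold %||% 10,
      seed = sim_seed)
    results[[sc_name]] <- run_replicates(pops, cfg)
  }
  base_name <- if ("baseline" %in% names(results)) "baseline" else names(results)[1]
  for (sc_name in names(results)) {
    summaries[[sc_name]] <- summarize_result(
      results[[sc_name]],
      baseline_result = if (sc_name == base_name) NULL else results[[base_name]])
  }
  comparison <- compare_scenarios(results, baseline = base_name)

  # --- outputs and manifest -------------------------------------------------
  manifest <- list(config = config, seed = seed,
                   algorithms = as.list(algorithms),
                   started = format(t0), files = list())
  out <- list(landscape = land, occurrences = occ,
              sdm = list(metrics = metrics, weights = weights),
              suitability = suit0, patches = patches, populations = pops,
              pool = pool, matrix = A, results = results,
              summaries = summaries, comparison = comparison)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wp <- function(name, writer) {
      path <- file.path(out_dir, name)
      writer(path)
      path
    }
    paths <- c(
      wp("sdm_metrics.csv", function(p) utils::write.csv(metrics, p, row.names = FALSE)),
      wp("suitability_initial.txt", function(p) write_pva_raster(suit0, p)),
      wp("landcover_initial.txt", function(p) write_pva_raster(mask0, p)),
      wp("patches.csv", function(p) utils::write.csv(data.frame(
        id = vapply(patches, `[[`, integer(1), "id"),
        n_cells = vapply(patches, `[[`, integer(1), "n_cells"),
        area_km2 = vapply(patches, `[[`, numeric(1), "area_km2"),
        total_suitability = vapply(patches, `[[`, numeric(1), "total_suitability"),
        K = vapply(pops, function(x) as.numeric(x$K), numeric(1)),
        N0_juv = vapply(pops, function(x) x$N[1], integer(1)),
        N0_sub = vapply(pops, function(x) x$N[2], integer(1)),
        N0_adult = vapply(pops, function(x) x$N[3], integer(1))), p, row.names = FALSE)),
      wp("comparison.csv", function(p) utils::write.csv(comparison$table, p, row.names = FALSE)))
    for (sc_name in names(summaries)) {
      paths <- c(paths, wp(paste0("summary_", sc_name, ".csv"), function(p)
        utils::write.csv(summaries[[sc_name]]$by_year, p, row.names = FALSE)))
    }
    manifest$files <- lapply(stats::setNames(paths, basename(paths)), function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
    manifest$finished <- format(Sys.time())
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out$manifest <- manifest
  invisible(out)
}

#' Compare scenario simulation results against a baseline
#'
#' Builds the per-decade effect table (change of the median abundance
#' percentage relative to the baseline scenario, with replicate-percentile
#' intervals) and, when climate-only, land-cover-only and combined scenarios
#' are all present, classifies their interaction per decade.
#'
#' @param results named list of `pva_sim_result` objects sharing one
#'   horizon, landscape and demography.
#' @param baseline name of the baseline scenario (default `"baseline"`).
#' @param decade_years simulation years to report (default every 10th year
#'   up to the horizon).
#' @param cc,lc,combined scenario names used for interaction classification.
#' @return list with `table` (scenario x year effects) and `interactions`
#'   (data.frame, possibly empty).
#' @export
compare_scenarios <- function(results, baseline = "baseline",
                              decade_years = NULL, cc = "CC", lc = "LC",
                              combined = "CCLC") {
  if (!baseline %in% names(results))
    stop("compare_scenarios(): baseline scenario '", baseline, "' not in results")
  horizons <- vapply(results, function(r) ncol(r$totals), integer(1))
  if (length(unique(horizons)) != 1)
    stop("compare_scenarios(): incompatible results - horizons differ")
  h <- horizons[1] - 1
  if (is.null(decade_years)) decade_years <- seq(10, h, by = 10)
  decade_years <- decade_years[decade_years <= h]
  rows <- list(); eff <- list()
  for (sc_name in names(results)) {
    s <- summarize_result(results[[sc_name]], results[[baseline]])
    sel <- s$by_year[s$by_year$year %in% decade_years, ]
    rows[[sc_name]] <- data.frame(scenario = sc_name, year = sel$year,
                                  rel_change = sel$rel_change,
                                  rel_lo = sel$rel_lo, rel_hi = sel$rel_hi)
    eff[[sc_name]] <- sel
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  interactions <- data.frame()
  if (all(c(cc, lc, combined) %in% names(results))) {
    for (y in decade_years) {
      e_cc <- eff[[cc]][eff[[cc]]$year == y, ]
      e_lc <- eff[[lc]][eff[[lc]]$year == y, ]
      e_cb <- eff[[combined]][eff[[combined]]$year == y, ]
      cls <- classify_interaction(
        e_cc$rel_change, e_lc$rel_change, e_cb$rel_change,
        interval_sum = c(e_cc$rel_lo + e_lc$rel_lo, e_cc$rel_hi + e_lc$rel_hi),
        interval_combined = c(e_cb$rel_lo, e_cb$rel_hi))
      interactions <- rbind(interactions, data.frame(
        year = y, effect_cc = e_cc$rel_change, effect_lc = e_lc$rel_change,
        effect_combined = e_cb$rel_change,
        classification = cls$classification))
    }
  }
  list(table = table, interactions = interactions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
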