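# Habitat-patch delineation by a neighborhood distance rule, population
# initialization and carrying-capacity tracking, and land-cover-change
# scenario generation.

#' Delineate habitat patches from a suitability map
#'
#' Cells at or above the suitability threshold are grouped into connected
#' components where two cells connect iff their centre-to-centre Euclidean
#' distance is at most `neighborhood_km`. The neighborhood rule treats
#' dispersal implicitly: clusters closer than the threshold form a single
#' population.
#'
#' @param suitability_map a [pva_raster] with values in \[0, 1\] or `NA`.
#' @param suitability_threshold cutoff in \[0, 1\] for a cell to count as
#'   habitat.
#' @param neighborhood_km linking distance in km (>= cell size); default 5.
#' @return list of patches, each a list with `id`, `cells` (matrix of row,
#'   col), `cell_index`, `n_cells`, `area_km2`, `total_suitability`,
#'   `centroid` (x, y in km). Empty list when no cell qualifies.
#' @export
delineate_patches <- function(suitability_map, suitability_threshold,
                              neighborhood_km = 5) {
  if (suitability_threshold < 0 || suitability_threshold > 1)
    stop("delineate_patches(): suitability_threshold must be in [0, 1]")
  cs <- suitability_map$cell_size_km
  if (neighborhood_km < cs)
    stop("delineate_patches(): neighborhood_km must be >= the cell size")
  vals <- suitability_map$values
  d <- dim(vals)
  suit <- which(!is.na(vals) & vals >= suitability_threshold)
  if (length(suit) == 0) return(list())
  rows <- ((suit - 1) %% d[1]) + 1
  cols <- ((suit - 1) %/% d[1]) + 1
  # offsets whose centre distance is within the neighborhood (half-plane to
  # avoid duplicate edges)
  rmax <- floor(neighborhood_km / cs)
  offs <- expand.grid(dr = -rmax:rmax, dc = 0:rmax)
  offs <- offs[(offs$dr^2 + offs$dc^2) * cs^2 <= neighborhood_km^2 &
                 !(offs$dc == 0 & offs$dr <= 0), , drop = FALSE]
  pos <- match(suit, suit)  # identity; lookup table below
  lut <- integer(prod(d)); lut[suit] <- seq_along(suit)
  edges <- list(); ne <- 0
  for (k in seq_len(nrow(offs))) {
    rr <- rows + offs$dr[k]; cc <- cols + offs$dc[k]
    ok <- rr >= 1 & rr <= d[1] & cc >= 1 & cc <= d[2]
    if (!any(ok)) next
    nb <- (cc[ok] - 1) * d[1] + rr[ok]
    hit <- lut[nb] > 0
    if (!any(hit)) next
    ne <- ne + 1
    edges[[ne]] <- cbind(which(ok)[hit], lut[nb[hit]])
  }
  if (ne > 0) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(suit) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  } else {
    comp <- seq_along(suit)
  }
  # stable ids in scan order of each component's first cell
  first <- tapply(seq_along(suit), comp, min)
  relabel <- match(comp, comp[sort(first)])
  patches <- vector("list", max(relabel))
  for (p in seq_len(max(relabel))) {
    i <- which(relabel == p)
    cells <- cbind(row = rows[i], col = cols[i])
    x <- suitability_map$origin[1] + (cols[i] - 0.5) * cs
    y <- suitability_map$origin[2] + (rows[i] - 0.5) * cs
    patches[[p]] <- list(
      id = p, cells = cells, cell_index = suit[i], n_cells = length(i),
      area_km2 = length(i) * cs^2,
      total_suitability = sum(vals[suit[i]]),
      centroid = c(x = mean(x), y = mean(y)))
  }
  patches
}

#' Initialize a population state for a patch
#'
#' Carrying capacity scales with patch size and habitat quality:
#' `K = round(density x total suitability x cell area)`. Initial abundance
#' is K apportioned across the three stages by the supplied stage
#' distribution with largest-remainder integer rounding.
#'
#' @param patch a patch from [delineate_patches()].
#' @param density_per_suitability_unit individuals per (summed suitability x
#'   km2) unit (> 0).
#' @param stage_distribution proportions per stage summing to 1 (typically
#'   the [stable_stage_distribution()] of the projection matrix).
#' @param cell_area_km2 area of one cell (default from the patch).
#' @return list with `patch_id`, `N` (integer per stage), `K`.
#' @export
initialize_population <- function(patch, density_per_suitability_unit,
                                  stage_distribution = rep(1 / 3, 3),
                                  cell_area_km2 = patch$area_km2 / patch$n_cells) {
  if (density_per_suitability_unit <= 0)
    stop("initialize_population(): density must be > 0")
  K <- round(density_per_suitability_unit * patch$total_suitability * cell_area_km2)
  N <- largest_remainder(stage_distribution, K)
  list(patch_id = patch$id, N = N, K = as.integer(K))
}

#' Update a population's carrying capacity from new habitat suitability
#'
#' Recomputes K by the initialization formula on the patch's member cells of
#' an updated suitability map; abundances are untouched (the ceiling rule
#' enforces the new K at the next projection step).
#'
#' @param population a population state from [initialize_population()].
#' @param new_total_suitability summed suitability of the patch cells on the
#'   updated map.
#' @param density_per_suitability_unit as at initialization.
#' @param cell_area_km2 cell area in km2.
#' @return the population state with updated `K`.
#' @export
update_carrying_capacity <- function(population, new_total_suitability,
                                     density_per_suitability_unit,
                                     cell_area_km2 = 1) {
  population$K <- as.integer(round(
    density_per_suitability_unit * new_total_suitability * cell_area_km2))
  population
}

#' Match patches across a habitat-map update by maximal cell overlap
#'
#' When a later map is re-delineated, each old patch is matched to the new
#' patch sharing the most cells; splits keep the id with the larger
#' fragment, merges take the lower old id. Old patches with no overlapping
#' new patch are unmatched (`NA`), which downstream sets K to 0 with a
#' warning.
#'
#' @param old_patches,new_patches patch lists from [delineate_patches()].
#' @return integer vector: for each old patch, the matched new patch id or
#'   `NA`.
#' @export
match_patches <- function(old_patches, new_patches) {
  if (length(new_patches) == 0) return(rep(NA_integer_, length(old_patches)))
  new_idx <- lapply(new_patches, `[[`, "cell_index")
  out <- rep(NA_integer_, length(old_patches))
  claimed <- rep(NA_integer_, length(new_patches))  # old id that claimed each new patch
  for (i in seq_along(old_patches)) {
    ov <- vapply(new_idx, function(ci) length(intersect(old_patches[[i]]$cell_index, ci)),
                 integer(1))
    if (all(ov == 0)) next
    j <- which.max(ov)
    if (is.na(claimed[j])) {
      claimed[j] <- i
      out[i] <- j
    }  # merge: a later (higher-id) old patch loses to the lower id
  }
  out
}

#' One year of land-cover conversion adjacent to unsuitable cells
#'
#' Converts `round(rate x current suitable-cell count)` suitable cells to
#' unsuitable, drawn uniformly among suitable cells having an unsuitable
#' cell within `adjacency_radius` (Chebyshev cell distance; the default 1 is
#' queen's-move adjacency). If the eligible frontier is smaller than the
#' quota, the remaining conversions fall back to the suitable cells nearest
#' to the unsuitable frontier.
#'
#' @param mask binary [pva_raster] (1 suitable, 0 unsuitable).
#' @param rate annual conversion rate in \[0, 1\].
#' @param adjacency_radius proximity radius in cells (>= 1).
#' @param seed integer seed.
#' @return the next-year binary mask.
#' @export
landcover_expansion_step <- function(mask, rate, adjacency_radius = 1, seed = 1) {
  if (rate < 0 || rate > 1) stop("landcover_expansion_step(): rate must be in [0, 1]")
  vals <- mask$values
  suit <- which(vals == 1)
  quota <- round(rate * length(suit))
  if (quota == 0 || length(suit) == 0) return(mask)
  d <- dim(vals)
  unsuit <- which(vals == 0)
  with_seed(derive_seed(seed, "lcc"), {
    if (length(unsuit) == 0) {
      take <- suit[sample.int(length(suit), min(quota, length(suit)))]
    } else {
      ur <- ((unsuit - 1) %% d[1]) + 1; uc <- ((unsuit - 1) %/% d[1]) + 1
      sr <- ((suit - 1) %% d[1]) + 1; sc <- ((suit - 1) %/% d[1]) + 1
      # Chebyshev distance from each suitable cell to the nearest unsuitable
      dist <- vapply(seq_along(suit), function(i)
        min(pmax(abs(sr[i] - ur), abs(sc[i] - uc))), numeric(1))
      eligible <- which(dist <= adjacency_radius)
      if (length(eligible) >= quota) {
        take <- suit[eligible[sample.int(length(eligible), quota)]]
      } else {
        # frontier fallback: everything eligible, then nearest-frontier cells
        rest <- setdiff(order(dist, sample.int(length(suit))), eligible)
        take <- suit[c(eligible, rest[seq_len(quota - length(eligible))])]
      }
    }
    vals[take] <- 0
  })
  pva_raster(vals, mask$cell_size_km, mask$origin, label = mask$label)
}

#' Build a yearly land-cover mask series for a scenario
#'
#' Intensification freezes the mask (land conversion stops: climate change
#' only); expansion iterates [landcover_expansion_step()] at the scenario's
#' annual rate, so the suitable-cell count is nonincreasing.
#'
#' @param initial_mask binary [pva_raster].
#' @param scenario list with `kind` (`"intensification"` or `"expansion"`),
#'   `rate` (default 0.01/yr), `adjacency_radius` (default 1), `seed`.
#' @param n_years number of yearly steps.
#' @return list of `n_years + 1` masks (year 0 is the initial mask).
#' @export
build_mask_series <- function(initial_mask, scenario, n_years) {
  kind <- match.arg(scenario$kind, c("intensification", "expansion"))
  out <- vector("list", n_years + 1)
  out[[1]] <- initial_mask
  if (kind == "intensification") {
    for (y in seq_len(n_years)) out[[y + 1]] <- initial_mask
    return(out)
  }
  rate <- if (is.null(scenario$rate)) 0.01 else scenario$rate
  radius <- if (is.null(scenario$adjacency_radius)) 1 else scenario$adjacency_radius
  seed <- if (is.null(scenario$seed)) 1 else scenario$seed
  for (y in seq_len(n_years)) {
    out[[y + 1]] <- landcover_expansion_step(out[[y]], rate, radius,
                                             seed = derive_seed(seed, "year", y))
  }
  out
}
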