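# Synthetic landscapes, occurrences, land-cover masks, and coarse GCM-like
# climate series with known ground truth. These generators define the study
# conditions for every downstream stage; each is a pure function of its
# arguments including the seed.

#' Generate a synthetic landscape with known habitat suitability
#'
#' Builds a square-celled grid carrying a ground-truth suitability surface
#' in \[0, 1\] and a small stack of environmental predictor layers. The
#' suitability is a smooth monotone (logistic) function of the first
#' predictor (`bio1`, an annual-mean-temperature-like field), so a
#' distribution model fitted to sampled occurrences can in principle recover
#' it. A second predictor (`bio12`, annual-precipitation-like) carries
#' seeded smooth spatial structure unrelated to suitability.
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param cell_size_km cell edge length in km (> 0); default 1 (a 1-km2 grid).
#' @param gradient character: `"linear"` (suitability rises smoothly from the
#'   west to the east edge), `"hill"` (radial peak at the grid centre), or
#'   `"flat"` (constant suitability `flat_value`).
#' @param flat_value suitability used when `gradient = "flat"`.
#' @param seed integer seed; identical seeds give bit-identical landscapes.
#' @return an object of class `pva_landscape`: list with `true_suitability`
#'   (a [pva_raster]), `predictors` (named list of [pva_raster]), and `seed`.
#' @export
gen_landscape <- function(rows, cols, cell_size_km = 1,
                          gradient = c("linear", "hill", "flat"),
                          flat_value = 0.5, seed = 1) {
  gradient <- match.arg(gradient)
  if (rows < 1 || cols < 1) stop("gen_landscape(): rows and cols must be >= 1")
  if (cell_size_km <= 0) stop("gen_landscape(): cell_size_km must be > 0")
  rows <- as.integer(rows); cols <- as.integer(cols)

  # column/row coordinates scaled to [0, 1] (degenerate 1-cell axis -> 0.5)
  u <- if (cols > 1) (seq_len(cols) - 1) / (cols - 1) else 0.5
  v <- if (rows > 1) (seq_len(rows) - 1) / (rows - 1) else 0.5
  U <- matrix(u, rows, cols, byrow = TRUE)
  V <- matrix(v, rows, cols)

  # bio1-like driver: west-east temperature ramp 14..22 degC (linear/flat),
  # or a radial gradient coolest at the central peak (hill) emulating a
  # cool-adapted montane species whose compact suitable core contracts
  # under warming
  if (gradient == "hill") {
    r <- sqrt((U - 0.5)^2 + (V - 0.5)^2)
    bio1 <- 14 + 25 * r               # cool summit, warm lowlands
  } else {
    bio1 <- 14 + 8 * U
  }

  suit <- switch(gradient,
    flat = matrix(flat_value, rows, cols),
    # logistic link centred mid-ramp; strictly increasing in bio1
    linear = stats::plogis((bio1 - 18) / 1.6),
    # steep decreasing link: suitability confined near the cool core
    hill = stats::plogis((18 - bio1) / 0.8))

  # independent smooth precipitation-like field from a few seeded Fourier modes
  bio12 <- with_seed(derive_seed(seed, "bio12"), {
    z <- matrix(0, rows, cols)
    for (k in 1:4) {
      fx <- stats::runif(1, 0.5, 3); fy <- stats::runif(1, 0.5, 3)
      ph <- stats::runif(2, 0, 2 * pi)
      amp <- stats::runif(1, 20, 60)
      z <- z + amp * sin(2 * pi * fx * U + ph[1]) * cos(2 * pi * fy * V + ph[2])
    }
    800 + z
  })

  structure(list(
    true_suitability = pva_raster(suit, cell_size_km, label = "truth"),
    predictors = list(
      bio1 = pva_raster(bio1, cell_size_km, label = "bio1"),
      bio12 = pva_raster(bio12, cell_size_km, label = "bio12")),
    seed = as.integer(seed)),
    class = "pva_landscape")
}

#' @export
print.pva_landscape <- function(x, ...) {
  d <- dim(x$true_suitability$values)
  cat(sprintf("<pva_landscape> %d x %d cells, predictors: %s\n",
              d[1], d[2], paste(names(x$predictors), collapse = ", ")))
  invisible(x)
}

#' Sample presence and background points from a landscape
#'
#' Presence cells are drawn with probability proportional to the true
#' suitability (suitability as a relative sampling intensity); background
#' points are drawn uniformly over the remaining land cells, excluding cells
#' that received a presence. Points sit at cell centres.
#'
#' @param landscape a `pva_landscape`.
#' @param n_presence,n_background numbers of points (each >= 1).
#' @param seed integer seed.
#' @return data.frame with columns `x`, `y` (km), `row`, `col`, `presence`
#'   (1 for presence, 0 for background).
#' @export
gen_occurrences <- function(landscape, n_presence, n_background, seed = 1) {
  if (n_presence < 1 || n_background < 1)
    stop("gen_occurrences(): n_presence and n_background must be >= 1")
  suit <- landscape$true_suitability
  w <- as.vector(suit$values)
  w[is.na(w)] <- 0
  if (all(w <= 0))
    stop("gen_occurrences(): cannot sample presences from an all-zero suitability landscape")
  n_cells <- length(w)
  with_seed(derive_seed(seed, "occ"), {
    pres_cells <- sample.int(n_cells, n_presence, replace = TRUE, prob = w)
    land <- setdiff(which(!is.na(as.vector(suit$values))), unique(pres_cells))
    if (length(land) == 0)
      stop("gen_occurrences(): no cells left for background sampling")
    bg_cells <- land[sample.int(length(land), n_background, replace = TRUE)]
    cells <- c(pres_cells, bg_cells)
    d <- dim(suit$values)
    rows <- ((cells - 1) %% d[1]) + 1
    cols <- ((cells - 1) %/% d[1]) + 1
    data.frame(
      x = suit$origin[1] + (cols - 0.5) * suit$cell_size_km,
      y = suit$origin[2] + (rows - 0.5) * suit$cell_size_km,
      row = rows, col = cols,
      presence = rep(c(1L, 0L), c(n_presence, n_background)))
  })
}

#' Generate a binary land-cover mask
#'
#' Marks a target fraction of cells as unsuitable land cover (mask value 0;
#' suitable cells are 1). With `clustering = TRUE` the unsuitable cells are
#' grown as contiguous blobs from a few random seed cells (breadth-first
#' frontier growth), emulating fragmented conversion; otherwise they are
#' scattered uniformly.
#'
#' @param landscape a `pva_landscape` (supplies the grid).
#' @param fraction_unsuitable fraction in \[0, 1\] of cells to mark unsuitable.
#' @param clustering logical; grow contiguous unsuitable blobs.
#' @param n_blobs number of blob seeds when clustering.
#' @param seed integer seed.
#' @return a binary [pva_raster] (1 suitable, 0 unsuitable); the unsuitable
#'   count is exactly `round(fraction_unsuitable * n_cells)`.
#' @export
gen_landcover_mask <- function(landscape, fraction_unsuitable, clustering = FALSE,
                               n_blobs = 3, seed = 1) {
  if (fraction_unsuitable < 0 || fraction_unsuitable > 1)
    stop("gen_landcover_mask(): fraction_unsuitable must be in [0, 1]")
  grid <- landscape$true_suitability
  d <- dim(grid$values)
  n_cells <- prod(d)
  k <- round(fraction_unsuitable * n_cells)
  mask <- matrix(1, d[1], d[2])
  if (k > 0) {
    with_seed(derive_seed(seed, "mask"), {
      if (!clustering) {
        mask[sample.int(n_cells, k)] <- 0
      } else {
        seeds <- sample.int(n_cells, min(n_blobs, k))
        converted <- logical(n_cells)
        converted[seeds] <- TRUE
        frontier <- seeds
        while (sum(converted) < k) {
          # candidate neighbours (4-neighbourhood) of converted cells
          rows <- ((frontier - 1) %% d[1]) + 1
          cols <- ((frontier - 1) %/% d[1]) + 1
          cand <- integer(0)
          for (off in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
            rr <- rows + off[1]; cc <- cols + off[2]
            ok <- rr >= 1 & rr <= d[1] & cc >= 1 & cc <= d[2]
            cand <- c(cand, (cc[ok] - 1) * d[1] + rr[ok])
          }
          cand <- unique(cand[!converted[cand]])
          if (length(cand) == 0) {  # blobs saturated; jump to a fresh seed
            cand <- which(!converted)[sample.int(sum(!converted), 1)]
          }
          take <- cand[sample.int(length(cand), min(length(cand), k - sum(converted)))]
          converted[take] <- TRUE
          frontier <- take
        }
        mask[converted] <- 0
      }
    })
  }
  pva_raster(mask, grid$cell_size_km, grid$origin, label = "landcover")
}

#' Generate a coarse GCM-like monthly climate series
#'
#' Emulates general-circulation-model output on a grid coarser than the
#' landscape: the fine monthly baselines are block-aggregated by
#' `coarse_factor`, then a linear trend and (optionally) seeded interannual
#' noise are applied per year. Year 0 with zero noise equals the aggregated
#' baseline exactly.
#'
#' @param baseline_temp,baseline_prec monthly baseline stacks: lists of 12
#'   [pva_raster] layers on the fine grid (temperature degC, precipitation
#'   mm/month).
#' @param trend_temp_per_year additive temperature trend, degC per year.
#' @param trend_prec_frac_per_year multiplicative precipitation trend per
#'   year (e.g. -0.002 for -0.2\%/yr).
#' @param n_years horizon; the series covers years 0..`n_years` inclusive.
#' @param coarse_factor integer aggregation factor (>= 1).
#' @param noise_sd_temp interannual temperature noise s.d. (degC, same draw
#'   for all months of a year).
#' @param noise_cv_prec interannual precipitation noise CV (lognormal,
#'   mean 1).
#' @param seed integer seed.
#' @return list of class `pva_gcm_series`: `years` (0..n_years), `temp` and
#'   `prec` (per year, a list of 12 coarse [pva_raster] layers),
#'   `coarse_factor`.
#' @export
gen_gcm_series <- function(baseline_temp, baseline_prec,
                           trend_temp_per_year = 0, trend_prec_frac_per_year = 0,
                           n_years = 30, coarse_factor = 1,
                           noise_sd_temp = 0, noise_cv_prec = 0, seed = 1) {
  if (coarse_factor < 1) stop("gen_gcm_series(): coarse_factor must be >= 1")
  if (n_years < 1) stop("gen_gcm_series(): n_years must be >= 1")
  stopifnot(length(baseline_temp) == 12, length(baseline_prec) == 12)
  ct <- lapply(baseline_temp, aggregate_raster, factor = coarse_factor)
  cp <- lapply(baseline_prec, aggregate_raster, factor = coarse_factor)
  years <- 0:n_years
  sig <- sqrt(log(1 + noise_cv_prec^2))
  with_seed(derive_seed(seed, "gcm"), {
    temp <- vector("list", length(years))
    prec <- vector("list", length(years))
    for (i in seq_along(years)) {
      y <- years[i]
      dt <- trend_temp_per_year * y +
        if (noise_sd_temp > 0) stats::rnorm(1, 0, noise_sd_temp) else 0
      fp <- (1 + trend_prec_frac_per_year * y) *
        if (noise_cv_prec > 0) stats::rlnorm(1, -sig^2 / 2, sig) else 1
      temp[[i]] <- lapply(ct, function(r) pva_raster(r$values + dt, r$cell_size_km, r$origin))
      prec[[i]] <- lapply(cp, function(r) pva_raster(pmax(r$values * fp, 0), r$cell_size_km, r$origin))
    }
    structure(list(years = years, temp = temp, prec = prec,
                   coarse_factor = as.integer(coarse_factor)),
              class = "pva_gcm_series")
  })
}
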