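test_that("patch delineation groups cells by the neighborhood distance rule", {
  full <- raster_of(matrix(0.8, 10, 10))
  p <- delineate_patches(full, 0.5, 5)
  expect_length(p, 1)
  expect_equal(p[[1]]$n_cells, 100)
  expect_equal(p[[1]]$area_km2, 100)
  expect_equal(p[[1]]$total_suitability, 80)

  expect_length(delineate_patches(raster_of(matrix(0.1, 5, 5)), 0.5, 5), 0)

  # two clusters beyond the 5-km rule stay separate
  vals2 <- matrix(0, 3, 12)
  vals2[2, 1:3] <- 0.9
  vals2[2, 10:12] <- 0.9  # nearest centers cols 3 and 10: 7 km apart
  two <- delineate_patches(raster_of(vals2), 0.5, 5)
  expect_length(two, 2)
  # shrinking the gap to 5 km merges them
  vals3 <- matrix(0, 3, 12)
  vals3[2, c(3, 8)] <- 0.9  # centers 5 km apart
  expect_length(delineate_patches(raster_of(vals3), 0.5, 5), 1)
  vals4 <- matrix(0, 3, 12)
  vals4[2, c(3, 9)] <- 0.9  # centers 6 km apart
  expect_length(delineate_patches(raster_of(vals4), 0.5, 5), 2)

  expect_error(delineate_patches(full, 1.5, 5), "\\[0, 1\\]")
  expect_error(delineate_patches(full, 0.5, 0.5), "cell size")
})

test_that("patch delineation matches the brute-force union-find oracle", {
  set.seed(31)
  for (i in 1:60) {
    nr <- sample(4:20, 1); nc <- sample(4:20, 1)
    vals <- matrix(stats::rbinom(nr * nc, 1, 0.35) * runif(nr * nc, 0.5, 1), nr, nc)
    nb <- sample(c(1, 2.5, 5), 1)
    got <- delineate_patches(raster_of(vals), 0.5, nb)
    oracle <- patch_oracle(vals, 0.5, nb)
    expect_equal(length(got), if (length(oracle)) max(oracle) else 0)
    # same partition: cells of each found patch share one oracle label
    suit <- which(!is.na(vals) & vals >= 0.5)
    for (p in got) {
      labs <- oracle[match(p$cell_index, suit)]
      expect_length(unique(labs), 1)
    }
  }
})

test_that("initialization scales K by patch size times suitability", {
  patch <- list(id = 1L, cells = cbind(1, 1:5), cell_index = 1:5, n_cells = 5L,
                area_km2 = 5, total_suitability = 12.5, centroid = c(x = 3, y = 1))
  pop <- initialize_population(patch, 10, stage_distribution = c(0.5, 0.25, 0.25))
  expect_equal(pop$K, 125L)
  expect_equal(sum(pop$N), 125)
  expect_equal(pop$N, c(63L, 31L, 31L))  # largest remainder
  zero <- patch; zero$total_suitability <- 0
  p0 <- initialize_population(zero, 10)
  expect_equal(p0$K, 0L)
  expect_equal(sum(p0$N), 0)
  # doubling suitability doubles K within rounding
  dbl <- patch; dbl$total_suitability <- 25
  expect_lte(abs(initialize_population(dbl, 10)$K - 2 * pop$K), 1)
  expect_error(initialize_population(patch, 0), "> 0")
})

test_that("carrying capacity tracks habitat while abundances persist", {
  patch <- list(id = 1L, cell_index = 1:4, n_cells = 4L, area_km2 = 4,
                total_suitability = 10, centroid = c(x = 1, y = 1))
  pop <- initialize_population(patch, 10, c(1, 1, 1) / 3)
  expect_equal(update_carrying_capacity(pop, 10, 10)$K, pop$K)
  half <- update_carrying_capacity(pop, 5, 10)
  expect_lte(abs(half$K - pop$K / 2), 1)
  expect_equal(half$N, pop$N)
  expect_equal(update_carrying_capacity(pop, 0, 10)$K, 0L)
})

test_that("patch matching is by maximal overlap with merge/split rules", {
  m1 <- matrix(0, 5, 12); m1[2:3, 1:3] <- 0.9; m1[2:3, 9:12] <- 0.9
  old <- delineate_patches(raster_of(m1), 0.5, 2)
  expect_length(old, 2)
  # new map loses the first cluster entirely
  m2 <- matrix(0, 5, 12); m2[2:3, 9:12] <- 0.9
  new <- delineate_patches(raster_of(m2), 0.5, 2)
  match <- match_patches(old, new)
  expect_true(is.na(match[1]))
  expect_equal(match[2], 1L)
})

test_that("expansion converts the quota adjacent to unsuitable frontier", {
  land <- gen_landscape(10, 10, 1, "flat", flat_value = 0.5, seed = 1)
  ones <- gen_landcover_mask(land, 0)
  expect_identical(landcover_expansion_step(ones, 0, seed = 2)$values, ones$values)
  zeros <- gen_landcover_mask(land, 1)
  expect_identical(landcover_expansion_step(zeros, 0.05, seed = 2)$values, zeros$values)

  vals <- matrix(1, 10, 10); vals[5, 5] <- 0  # 99 suitable, one seed
  m <- pva_raster(vals)
  nxt <- landcover_expansion_step(m, 0.01, adjacency_radius = 1, seed = 3)
  conv <- which(m$values == 1 & nxt$values == 0)
  expect_length(conv, 1)  # round(0.01 * 99) = 1
  rr <- ((conv - 1) %% 10) + 1; cc <- ((conv - 1) %/% 10) + 1
  expect_lte(max(abs(rr - 5), abs(cc - 5)), 1)  # queen-adjacent to the seed
})

test_that("mask series follow their scenario and never regain habitat", {
  land <- gen_landscape(12, 12, 1, "flat", flat_value = 0.5, seed = 2)
  m0 <- gen_landcover_mask(land, 0.1, clustering = TRUE, seed = 3)
  flat <- build_mask_series(m0, list(kind = "intensification"), 8)
  expect_length(flat, 9)
  for (m in flat) expect_identical(m$values, m0$values)
  exp_series <- build_mask_series(m0, list(kind = "expansion", rate = 0.05, seed = 4), 8)
  counts <- vapply(exp_series, function(m) sum(m$values == 1), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # per-step quota matches the rounded geometric recursion
  for (y in 1:8)
    expect_equal(counts[y + 1], counts[y] - round(0.05 * counts[y]))
})
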