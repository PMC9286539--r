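test_that("threshold, confusion metrics and TSS follow their definitions", {
  expect_equal(no_omission_threshold(c(0.3, 0.5, 0.7)), 0.3)
  expect_equal(no_omission_threshold(0.42), 0.42)
  expect_error(no_omission_threshold(numeric(0)), "empty")

  expect_equal(confusion_metrics(c(0.9, 0.8), c(0.1, 0.2), 0.5),
               c(sensitivity = 1, specificity = 1))
  expect_equal(confusion_metrics(c(0.9, 0.8), c(0.1, 0.2), 0)[["specificity"]], 0)
  cm <- confusion_metrics(c(0.6, 0.2), c(0.5, 0.1, 0.7, 0.05, 0.3), 0.55)
  expect_equal(unname(cm), c(0.5, 0.8))

  expect_equal(compute_tss(1, 1), 1)
  expect_equal(compute_tss(0.56, 0.4), -0.04)
  expect_error(compute_tss(1.2, 0.5), "\\[0, 1\\]")
})

test_that("rank-based AUC matches brute-force pair counting", {
  expect_equal(compute_auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_equal(compute_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(compute_auc(c(5, 6), c(1, 2)), 1)
  set.seed(42)
  for (i in 1:50) {
    np <- sample(1:25, 1); nb <- sample(1:25, 1)
    # discrete support forces ties
    p <- sample(seq(0, 1, 0.1), np, replace = TRUE)
    b <- sample(seq(0, 1, 0.1), nb, replace = TRUE)
    expect_equal(compute_auc(p, b), auc_oracle(p, b))
  }
  expect_error(compute_auc(numeric(0), 1), "nonempty")
})

test_that("all three algorithms separate a perfectly separable predictor", {
  land <- gen_landscape(20, 20, 1, "linear", seed = 1)
  pts <- data.frame(row = rep(1:10, 2), col = rep(c(20, 1), each = 10),
                    presence = rep(c(1L, 0L), each = 10))
  test_pts <- data.frame(row = rep(1:5, 2), col = rep(c(19, 2), each = 5),
                         presence = rep(c(1L, 0L), each = 5))
  X <- data.frame(bio1 = land$predictors$bio1$values[cbind(test_pts$row, test_pts$col)],
                  bio12 = land$predictors$bio12$values[cbind(test_pts$row, test_pts$col)])
  for (alg in c("glm", "maxent_like", "random_forest")) {
    m <- fit_sdm(pts, land$predictors, alg, seed = 2)
    s <- predict(m, X)
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(compute_auc(s[test_pts$presence == 1], s[test_pts$presence == 0]), 1)
    # refitting with the same seed reproduces identical scores
    s2 <- predict(fit_sdm(pts, land$predictors, alg, seed = 2), X)
    expect_identical(s, s2)
  }
  expect_error(fit_sdm(pts, land$predictors, "boosting"), "arg")
  expect_error(fit_sdm(pts[1:12, ], land$predictors, "glm"), "at least 10")
})

test_that("fivefold evaluation: identity, separable and permutation-null AUC", {
  land <- gen_landscape(40, 40, 1, "hill", seed = 21)
  occ <- gen_occurrences(land, 200, 400, seed = 22)
  for (alg in c("glm", "maxent_like", "random_forest")) {
    ev <- kfold_evaluate(occ, land$predictors, alg, k = 5, seed = 23)
    expect_equal(nrow(ev), 5)
    expect_equal(ev$tss, ev$sensitivity + ev$specificity - 1, tolerance = 1e-12)
    # noise-free gradient landscape: strong out-of-fold discrimination
    expect_gt(mean(ev$auc), 0.9)
  }
  # perfectly separable synthetic data: every fold reaches AUC 1
  sep <- data.frame(row = rep(1:20, 4),
                    col = rep(c(39, 40, 1, 2), each = 20),
                    presence = rep(c(1L, 0L), each = 40))
  land_lin <- gen_landscape(20, 40, 1, "linear", seed = 25)
  for (alg in c("glm", "maxent_like", "random_forest")) {
    evs <- kfold_evaluate(sep, land_lin$predictors, alg, k = 5, seed = 26)
    expect_equal(evs$auc, rep(1, 5))
  }
  # permuted labels: no signal left
  perm <- occ
  set.seed(99)
  perm$presence <- sample(occ$presence)
  ev0 <- kfold_evaluate(perm, land$predictors, "glm", k = 5, seed = 24)
  expect_gt(mean(ev0$auc), 0.35)
  expect_lt(mean(ev0$auc), 0.65)
  expect_error(kfold_evaluate(occ, land$predictors, "glm", k = 1), ">= 2")
  expect_error(kfold_evaluate(occ[occ$presence == 0 | seq_len(nrow(occ)) <= 3, ],
                              land$predictors, "glm", k = 5), "exceeds")
})

test_that("ensemble weighting is an AUC-weighted mean bounded by its members", {
  a <- raster_of(matrix(0.8, 2, 2)); b <- raster_of(matrix(0.4, 2, 2))
  expect_equal(ensemble_weighted_mean(list(a), 0.9)$values, a$values)
  e <- ensemble_weighted_mean(list(a, b), c(0.75, 0.25))
  expect_equal(e$values[1, 1], 0.7)
  expect_equal(ensemble_weighted_mean(list(a, b), c(0.5, 0.5))$values[1, 1], 0.6)
  set.seed(3)
  maps <- lapply(1:4, function(i) raster_of(matrix(runif(25), 5, 5)))
  w <- runif(4)
  ew <- ensemble_weighted_mean(maps, w)
  lo <- Reduce(pmin, lapply(maps, `[[`, "values"))
  hi <- Reduce(pmax, lapply(maps, `[[`, "values"))
  expect_true(all(ew$values >= lo - 1e-12 & ew$values <= hi + 1e-12))
  expect_error(ensemble_weighted_mean(list(a, b), c(0, 0)), "zero")
  expect_error(ensemble_weighted_mean(list(a, raster_of(matrix(1, 3, 3))), c(1, 1)),
               "grid mismatch")
})

test_that("land-cover masking is a pointwise, idempotent product", {
  m <- raster_of(matrix(c(0.8, 0.6, 0.4, 0.2), 2, 2))
  ones <- raster_of(matrix(1, 2, 2)); zeros <- raster_of(matrix(0, 2, 2))
  expect_equal(apply_landcover_mask(m, ones)$values, m$values)
  expect_true(all(apply_landcover_mask(m, zeros)$values == 0))
  mask <- raster_of(matrix(c(0, 1, 1, 0), 2, 2))
  once <- apply_landcover_mask(m, mask)
  expect_equal(once$values[1, 1], 0)
  expect_equal(once$values[2, 1], 0.6)
  expect_equal(apply_landcover_mask(once, mask)$values, once$values)
})

test_that("suitable area counts thresholded cells and percent change", {
  m <- raster_of(matrix(0.6, 10, 10))
  expect_equal(suitable_area(m, 0.5)$area_km2, 100)
  expect_equal(suitable_area(m, 0.7)$area_km2, 0)
  sa <- suitable_area(raster_of(matrix(c(rep(0.9, 39), rep(0.1, 61)), 10, 10)),
                      0.5, reference_area_km2 = 100)
  expect_equal(sa$area_km2, 39)
  expect_equal(sa$percent_change, -61)
  withNA <- raster_of(matrix(c(NA, 0.9, 0.2, 0.8), 2, 2))
  expect_equal(suitable_area(withNA, 0.5)$n_cells, 2)
})
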