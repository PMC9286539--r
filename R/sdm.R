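# Presence/background suitability modelling: three algorithms, fivefold
# evaluation with the no-omission threshold, AUC-weighted ensembling, and
# land-cover masking.

# extract predictor values at point rows/cols into a design data.frame
extract_predictors <- function(points, predictor_layers) {
  out <- lapply(predictor_layers, function(r) {
    r$values[cbind(points$row, points$col)]
  })
  as.data.frame(out)
}

#' Fit a presence/background suitability model
#'
#' Three interchangeable algorithms: `"glm"` (binomial GLM with linear
#' terms), `"maxent_like"` (ridge-regularized logistic regression on a
#' linear + quadratic feature expansion — an approximation of maxent's
#' exponential model on presence/background data, not a reimplementation of
#' maxent itself), and `"random_forest"` (probability forest). All map any
#' predictor vector to a score in \[0, 1\] and are deterministic given
#' `seed`.
#'
#' @param points data.frame with `row`, `col`, `presence` (1/0), as from
#'   [gen_occurrences()].
#' @param predictor_layers named list of [pva_raster] predictor layers on a
#'   common grid.
#' @param algorithm one of `"maxent_like"`, `"glm"`, `"random_forest"`.
#' @param seed integer seed (matters for the forest).
#' @return object of class `pva_sdm` with a [predict][predict.pva_sdm] method.
#' @export
fit_sdm <- function(points, predictor_layers,
                    algorithm = c("maxent_like", "glm", "random_forest"),
                    seed = 1) {
  algorithm <- match.arg(algorithm)
  np <- sum(points$presence == 1); nb <- sum(points$presence == 0)
  if (np < 10 || nb < 10)
    stop("fit_sdm(): need at least 10 presence and 10 background points")
  X <- extract_predictors(points, predictor_layers)
  if (all(vapply(X, function(v) length(unique(v)) == 1, logical(1))))
    stop("fit_sdm(): degenerate design - all predictors are constant")
  y <- as.integer(points$presence)
  dup <- unique(X[y == 1, , drop = FALSE])
  bgu <- unique(X[y == 0, , drop = FALSE])
  if (nrow(dup) == 1 && nrow(bgu) == 1 && all(dup == bgu))
    stop("fit_sdm(): degenerate design - presences identical to background")

  fit <- with_seed(derive_seed(seed, "sdm", algorithm), {
    switch(algorithm,
      glm = suppressWarnings(
        stats::glm(y ~ ., data = cbind(y = y, X), family = stats::binomial())),
      maxent_like = {
        M <- as.matrix(X)
        feats <- cbind(M, M^2)
        colnames(feats) <- c(colnames(M), paste0(colnames(M), "_sq"))
        glmnet::glmnet(feats, y, family = "binomial", alpha = 0,
                       lambda = 0.01, standardize = TRUE)
      },
      random_forest = randomForest::randomForest(
        x = X, y = factor(y, levels = c(0, 1)), ntree = 500))
  })
  structure(list(algorithm = algorithm, fit = fit,
                 predictor_names = names(predictor_layers)),
            class = "pva_sdm")
}

#' Predict suitability scores from a fitted model
#'
#' @param object a `pva_sdm`.
#' @param newdata data.frame of predictor values (columns named as the
#'   training layers).
#' @param ... unused.
#' @return numeric scores in \[0, 1\].
#' @export
predict.pva_sdm <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[, object$predictor_names, drop = FALSE]
  switch(object$algorithm,
    glm = as.numeric(stats::predict(object$fit, newdata, type = "response")),
    maxent_like = {
      M <- as.matrix(newdata)
      feats <- cbind(M, M^2)
      as.numeric(stats::predict(object$fit, feats, type = "response"))
    },
    random_forest = as.numeric(
      stats::predict(object$fit, newdata, type = "prob")[, "1"]))
}

#' Predict a suitability map over predictor layers
#'
#' @param model a `pva_sdm`.
#' @param predictor_layers named list of [pva_raster] layers on one grid.
#' @param label optional timestamp label for the output map.
#' @return a [pva_raster] of scores in \[0, 1\]; cells missing in any
#'   predictor are `NA`.
#' @export
predict_map <- function(model, predictor_layers, label = NULL) {
  template <- predictor_layers[[1]]
  vals <- lapply(predictor_layers, function(r) as.vector(r$values))
  df <- as.data.frame(vals)
  ok <- stats::complete.cases(df)
  scores <- rep(NA_real_, nrow(df))
  if (any(ok)) scores[ok] <- predict(model, df[ok, , drop = FALSE])
  pva_raster(matrix(scores, nrow(template$values), ncol(template$values)),
             template$cell_size_km, template$origin, label = label)
}

#' No-omission binarization threshold
#'
#' The minimum predicted score among training presences; binarizing the
#' training set at this threshold omits no presence (training sensitivity 1).
#' Held-out presences may still fall below it.
#'
#' @param presence_scores numeric vector of presence scores (nonempty).
#' @return the threshold.
#' @export
no_omission_threshold <- function(presence_scores) {
  if (length(presence_scores) == 0)
    stop("no_omission_threshold(): empty presence scores")
  min(presence_scores)
}

#' Sensitivity and specificity at a threshold
#'
#' Sensitivity is the fraction of presence scores at or above the threshold;
#' specificity the fraction of background scores below it.
#'
#' @param presence_scores,background_scores nonempty numeric score vectors.
#' @param threshold binarization cutoff.
#' @return named numeric vector `c(sensitivity, specificity)`.
#' @export
confusion_metrics <- function(presence_scores, background_scores, threshold) {
  if (length(presence_scores) == 0 || length(background_scores) == 0)
    stop("confusion_metrics(): score sets must be nonempty")
  c(sensitivity = mean(presence_scores >= threshold),
    specificity = mean(background_scores < threshold))
}

#' True skill statistic
#'
#' TSS = sensitivity + specificity - 1, in \[-1, 1\].
#'
#' @param sensitivity,specificity values in \[0, 1\].
#' @return the TSS.
#' @export
compute_tss <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) || any(specificity < 0 | specificity > 1))
    stop("compute_tss(): sensitivity and specificity must be in [0, 1]")
  sensitivity + specificity - 1
}

#' Rank-based AUC of presence vs background scores
#'
#' The Mann-Whitney statistic: the probability that a random presence scores
#' above a random background point, ties counting one half.
#'
#' @param presence_scores,background_scores nonempty numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np == 0 || nb == 0) stop("compute_auc(): score sets must be nonempty")
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Fivefold evaluation of a suitability model
#'
#' Stratified random partition of presences and background points into `k`
#' folds; for each fold the model is fitted on the remaining folds, the
#' no-omission threshold is taken on the training presences, and
#' sensitivity, specificity, AUC and TSS are computed on the held-out fold.
#'
#' @param points,predictor_layers,algorithm,seed as in [fit_sdm()].
#' @param k number of folds (default 5; at least 2, at most the number of
#'   presences).
#' @return data.frame with one row per fold: `fold`, `algorithm`,
#'   `sensitivity`, `specificity`, `auc`, `tss`, `threshold`.
#' @export
kfold_evaluate <- function(points, predictor_layers, algorithm, k = 5, seed = 1) {
  np <- sum(points$presence == 1)
  if (k < 2) stop("kfold_evaluate(): k must be >= 2")
  if (k > np) stop("kfold_evaluate(): k exceeds the number of presences")
  fold <- integer(nrow(points))
  with_seed(derive_seed(seed, "folds"), {
    for (cls in c(1L, 0L)) {
      idx <- which(points$presence == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    train <- points[fold != f, , drop = FALSE]
    test <- points[fold == f, , drop = FALSE]
    model <- fit_sdm(train, predictor_layers, algorithm, seed = seed)
    thr <- no_omission_threshold(
      predict(model, extract_predictors(train[train$presence == 1, ], predictor_layers)))
    ps <- predict(model, extract_predictors(test[test$presence == 1, , drop = FALSE], predictor_layers))
    bs <- predict(model, extract_predictors(test[test$presence == 0, , drop = FALSE], predictor_layers))
    cm <- confusion_metrics(ps, bs, thr)
    rows[[f]] <- data.frame(
      fold = f, algorithm = algorithm,
      sensitivity = cm[["sensitivity"]], specificity = cm[["specificity"]],
      auc = compute_auc(ps, bs),
      tss = compute_tss(cm[["sensitivity"]], cm[["specificity"]]),
      threshold = thr)
  }
  do.call(rbind, rows)
}

#' Performance-weighted ensemble mean of suitability maps
#'
#' Per-cell weighted mean of member maps with weights proportional to each
#' member's AUC (weights sum to 1).
#'
#' @param member_maps list of [pva_raster] maps on a common grid.
#' @param member_aucs numeric AUCs in \[0, 1\], one per member; must not all
#'   be zero.
#' @return a [pva_raster]; bounded cell-wise by the member minima and maxima.
#' @export
ensemble_weighted_mean <- function(member_maps, member_aucs) {
  if (length(member_maps) < 1) stop("ensemble_weighted_mean(): need >= 1 member")
  if (length(member_maps) != length(member_aucs))
    stop("ensemble_weighted_mean(): one AUC per member map required")
  if (any(member_aucs < 0 | member_aucs > 1))
    stop("ensemble_weighted_mean(): AUCs must be in [0, 1]")
  if (sum(member_aucs) <= 0) stop("ensemble_weighted_mean(): all weights are zero")
  for (m in member_maps[-1]) stop_unless_same_grid(member_maps[[1]], m, "member maps")
  w <- member_aucs / sum(member_aucs)
  acc <- member_maps[[1]]$values * w[1]
  if (length(member_maps) > 1)
    for (i in 2:length(member_maps)) acc <- acc + member_maps[[i]]$values * w[i]
  pva_raster(acc, member_maps[[1]]$cell_size_km, member_maps[[1]]$origin,
             label = member_maps[[1]]$label)
}

#' Apply a binary land-cover mask to a suitability map
#'
#' Per-cell product: cells with unsuitable land cover (mask 0) become
#' exactly 0. Idempotent for binary masks.
#'
#' @param map a [pva_raster] suitability map.
#' @param mask a binary [pva_raster] on the same grid.
#' @return the masked [pva_raster].
#' @export
apply_landcover_mask <- function(map, mask) {
  stop_unless_same_grid(map, mask, "map and mask")
  pva_raster(map$values * mask$values, map$cell_size_km, map$origin,
             label = map$label)
}

#' Suitable area of a thresholded map
#'
#' @param map a [pva_raster] suitability map; `NA` cells are excluded.
#' @param threshold suitability cutoff in \[0, 1\].
#' @param reference_area_km2 optional reference area; when given, the
#'   percent change relative to it is reported.
#' @return list with `area_km2`, `n_cells`, and `percent_change` (`NA`
#'   without a reference).
#' @export
suitable_area <- function(map, threshold, reference_area_km2 = NULL) {
  if (threshold < 0 || threshold > 1)
    stop("suitable_area(): threshold must be in [0, 1]")
  n <- sum(map$values >= threshold, na.rm = TRUE)
  area <- n * map$cell_size_km^2
  pc <- if (is.null(reference_area_km2)) NA_real_ else
    100 * (area - reference_area_km2) / reference_area_km2
  list(area_km2 = area, n_cells = n, percent_change = pc)
}
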