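test_that("dominant eigenvalue matches closed forms on 3x3 matrices", {
  expect_equal(dominant_eigenvalue(diag(3)), 1)
  A <- rbind(c(0, 0, 2), c(0.5, 0, 0), c(0, 0.5, 0))
  expect_equal(dominant_eigenvalue(A), 0.5^(1 / 3), tolerance = 1e-10)
  expect_equal(dominant_eigenvalue(cycle_matrix()), 1, tolerance = 1e-10)
  expect_error(dominant_eigenvalue(matrix(1, 2, 3)), "square")
  # equals the modulus-largest root of the characteristic polynomial
  set.seed(8)
  for (i in 1:20) {
    M <- matrix(runif(9), 3, 3)
    roots <- polyroot(c(-det(M),
                        M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1] +
                          M[1, 1] * M[3, 3] - M[1, 3] * M[3, 1] +
                          M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2],
                        -sum(diag(M)), 1))
    expect_equal(dominant_eigenvalue(M), max(Mod(roots)), tolerance = 1e-10)
  }
})

test_that("stable stage distribution is the Perron vector with uniform fallback", {
  expect_equal(stable_stage_distribution(cycle_matrix()), c(0.5, 0.25, 0.25),
               tolerance = 1e-10)
  expect_equal(stable_stage_distribution(diag(3)), rep(1 / 3, 3))
  set.seed(9)
  for (i in 1:20) {
    M <- matrix(runif(9, 0.05, 1), 3, 3)
    v <- stable_stage_distribution(M)
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_true(all(v >= 0))
    expect_equal(as.vector(M %*% v), dominant_eigenvalue(M) * v, tolerance = 1e-8)
  }
})

test_that("error minimization inverts noise-free tables exactly", {
  A <- plant_matrix()
  tab <- gen_stage_counts(demography_truth(A, 8, c(600, 300, 300)))
  fit <- error_minimize(tab)
  expect_lt(max(abs(fit$matrix - A)), 1e-6)
  expect_lt(fit$residual, 1e-12)
  expect_equal(fit$lambda, dominant_eigenvalue(A), tolerance = 1e-8)
})

test_that("a minimal two-year table reproduces the hand-solved rates", {
  # consistent 2-year census built by hand from chosen rates
  tab <- data.frame(
    year = 1:2, n_juv = c(100, 100 * 0.4 + 50 * 0.1 + 40 * 1.5),
    n_sub = c(50, 100 * 0.3 + 50 * 0.5 + 40 * 0.05),
    n_adult = c(40, 100 * 0.02 + 50 * 0.25 + 40 * 0.6),
    t_jj = 40, t_js = 30, t_ja = 2, t_ss = 25, t_sa = 12.5,
    t_as = 2, t_aa = 24, rec_sub = 5, rec_adult = 60,
    deaths_juv = 28, deaths_sub = 12.5, deaths_adult = 14)
  fit <- error_minimize(tab)
  hand <- rbind(c(0.40, 0.10, 1.50),
                c(0.30, 0.50, 0.05),
                c(0.02, 0.25, 0.60))
  expect_equal(unname(unclass(fit$matrix)), hand, tolerance = 1e-8)
  expect_lt(fit$residual, 1e-12)
})

test_that("a perturbed count yields a positive residual but a close lambda", {
  A <- plant_matrix()
  tab <- gen_stage_counts(demography_truth(A, 8, c(600, 300, 300)))
  tab$n_sub[4] <- tab$n_sub[4] * 1.1
  fit <- error_minimize(tab)
  expect_gt(fit$residual, 0)
  expect_lt(abs(fit$lambda - dominant_eigenvalue(A)), 0.05)
})

test_that("the fitter rejects infeasible tables", {
  tab <- gen_stage_counts(demography_truth(plant_matrix(), 4, c(60, 30, 30)))
  bad <- tab; bad$n_juv[2] <- -5
  expect_error(error_minimize(bad), "nonnegative")
  zero <- tab; zero$n_adult <- 0
  expect_error(error_minimize(zero), "all-zero")
  expect_error(error_minimize(tab[1, ]), "at least 2")
})

test_that("bootstrap pools capture the truth and degenerate correctly", {
  A <- plant_matrix()
  tab0 <- gen_stage_counts(demography_truth(A, 10, c(600, 300, 300)))
  p1 <- build_matrix_pool(tab0, 1)
  expect_length(p1$matrices, 1)
  expect_lt(max(abs(p1$matrices[[1]] - A)), 1e-6)
  # noise-free table: every bootstrap refit equals the truth (zero variance)
  p3 <- build_matrix_pool(tab0, 10, seed = 2)
  expect_lt(max(abs(p3$lambda - dominant_eigenvalue(A))), 1e-6)

  tabn <- gen_stage_counts(demography_truth(A, 10, c(600, 300, 300),
                                            observation_noise_cv = 0.08), seed = 5)
  pool <- build_matrix_pool(tabn, 200, seed = 3)
  lam <- sort(pool$lambda)
  truth <- dominant_eigenvalue(A)
  expect_lte(lam[ceiling(0.025 * 200)], truth)
  expect_gte(lam[ceiling(0.975 * 200)], truth)
  # every member respects the matrix invariants
  for (m in pool$matrices) expect_silent(leslie_matrix(m))
  # determinism
  pool2 <- build_matrix_pool(tabn, 200, seed = 3)
  expect_identical(pool$lambda, pool2$lambda)
})

test_that("percentile selection is nearest-rank on the lambda-sorted pool", {
  mats <- lapply(seq(0.90, 1.00, 0.01), function(l) l * diag(c(1, 0.5, 0.5)))
  pool <- structure(list(matrices = mats,
                         lambda = vapply(mats, dominant_eigenvalue, numeric(1)),
                         resample = seq_along(mats) - 1L, site = NULL),
                    class = "pva_matrix_pool")
  sel <- select_percentile_matrices(pool)
  expect_equal(attr(sel[["p2.5"]], "lambda"), 0.90)
  expect_equal(attr(sel[["p50"]], "lambda"), 0.95)
  expect_equal(attr(sel[["p97.5"]], "lambda"), 1.00)
  single <- structure(list(matrices = mats[1], lambda = pool$lambda[1],
                           resample = 0L, site = NULL), class = "pva_matrix_pool")
  s1 <- select_percentile_matrices(single)
  expect_equal(attr(s1[["p2.5"]], "lambda"), attr(s1[["p97.5"]], "lambda"))
  # brute-force sort oracle over random pools
  set.seed(10)
  for (i in 1:200) {
    n <- sample(1:40, 1)
    lam <- round(runif(n, 0.8, 1.2), 3)
    pl <- structure(list(matrices = lapply(lam, function(l) l * diag(3)),
                         lambda = lam, resample = seq_len(n) - 1L, site = NULL),
                    class = "pva_matrix_pool")
    sel <- select_percentile_matrices(pl, c(2.5, 50, 97.5))
    srt <- sort(lam)
    expect_equal(attr(sel[["p2.5"]], "lambda"), srt[max(1, ceiling(0.025 * n))])
    expect_equal(attr(sel[["p50"]], "lambda"), srt[max(1, ceiling(0.5 * n))])
    expect_equal(attr(sel[["p97.5"]], "lambda"), srt[max(1, ceiling(0.975 * n))])
  }
})

test_that("pools from near-stationary truths bracket lambda = 1", {
  # truth lambda ~ 1: the percentile bracket spans decline and growth
  A <- low_survival_matrix()
  lamA <- dominant_eigenvalue(A)
  A[1, 3] <- A[1, 3] * (1 / lamA)^3  # nudge fecundity toward lambda ~ 1
  A <- leslie_matrix(A)
  tab <- gen_stage_counts(demography_truth(A, 10, c(500, 300, 300),
                                           observation_noise_cv = 0.1), seed = 11)
  pool <- build_matrix_pool(tab, 150, seed = 12)
  sel <- select_percentile_matrices(pool)
  expect_lt(attr(sel[["p2.5"]], "lambda"), attr(sel[["p97.5"]], "lambda"))
  expect_lt(attr(sel[["p2.5"]], "lambda"), 1.0)
})
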