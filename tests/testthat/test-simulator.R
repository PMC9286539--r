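test_that("environmental multipliers have the configured moments and correlation", {
  A <- low_survival_matrix()
  # zero CVs: all multipliers exactly 1
  m0 <- draw_env_multipliers(A, stochasticity_spec(0, 0), seed = 1)
  expect_identical(m0, matrix(1, 3, 3))

  spec <- stochasticity_spec(0.20, 0.10)
  n <- 20000
  fec <- surv_big <- surv_other <- numeric(n)
  set.seed(77)
  for (i in 1:n) {
    m <- draw_env_multipliers(A, spec)
    fec[i] <- m[1, 3]        # adult reproduction
    surv_big[i] <- m[2, 2]   # largest survival entry of the subadult column
    surv_other[i] <- m[3, 2]
  }
  expect_lt(abs(mean(fec) - 1), 0.01)
  expect_lt(abs(mean(surv_big) - 1), 0.01)
  expect_lt(abs(stats::sd(fec) / mean(fec) - 0.20), 0.01)
  expect_lt(abs(stats::sd(surv_big) / mean(surv_big) - 0.10), 0.005)
  # the largest survival deviate is anticorrelated with the others
  expect_lt(stats::cor(surv_big, surv_other), -0.3)
  # effective survival sums never exceed 1
  set.seed(78)
  for (i in 1:200) {
    eff <- plant_matrix() * draw_env_multipliers(plant_matrix(), spec)
    cs <- colSums(eff * rbind(c(TRUE, FALSE, FALSE), TRUE, TRUE))
    expect_true(all(cs <= 1 + 1e-12))
  }
})

test_that("ceiling truncation scales proportionally to exactly K", {
  expect_equal(apply_ceiling(c(10L, 5L, 5L), 100), c(10L, 5L, 5L))
  expect_equal(apply_ceiling(c(60L, 40L, 20L), 100), c(50L, 33L, 17L))
  expect_equal(apply_ceiling(c(60L, 40L, 20L), 0), c(0L, 0L, 0L))
  set.seed(12)
  for (i in 1:100) {
    N <- as.integer(sample(0:500, 3, TRUE)); K <- sample(0:600, 1)
    out <- apply_ceiling(N, K)
    expect_true(all(out >= 0))
    expect_lte(sum(out), K)
    if (sum(N) <= K) expect_identical(out, N) else expect_equal(sum(out), K)
  }
})

test_that("harvest rules respect timing, minimum size and apportionment", {
  juv <- harvest_spec("JUV")
  all_ <- harvest_spec("ALL")
  # below the minimum population size: never harvested
  expect_equal(harvest_population(c(20L, 10L, 10L), juv, 2)$harvested, 0L)
  # off-years: no harvest
  expect_equal(harvest_population(c(100L, 50L, 50L), juv, 3)$harvested, 0L)
  # availability cap on juveniles
  h <- harvest_population(c(3L, 60L, 60L), juv, 2)
  expect_equal(h$harvested, 3L)
  expect_equal(h$N, c(0L, 60L, 60L))
  # proportional apportionment with stage-order tie-break
  h2 <- harvest_population(c(60L, 30L, 10L), all_, 2)
  expect_equal(h2$harvested, 5L)
  expect_equal(c(60L, 30L, 10L) - h2$N, c(3L, 2L, 0L))
  # ALL capped by total availability above the threshold
  h3 <- harvest_population(c(50L, 1L, 1L), harvest_spec("ALL", quota = 100), 2)
  expect_equal(h3$harvested, 52L)
  expect_equal(h3$N, c(0L, 0L, 0L))
})

test_that("projection has the right deterministic limit and fixed point", {
  B <- cycle_matrix()
  N <- c(200, 100, 100)  # stable stage distribution of the lambda = 1 cycle
  expect_equal(step_population(N, B, K = Inf, rounding = "none"), N)
  stepped <- step_population(N, B, K = Inf, rounding = "round")
  expect_true(all(abs(stepped - N) <= 1))
  expect_equal(step_population(c(10, 10, 10), matrix(0, 3, 3), K = Inf,
                               rounding = "round"), c(0L, 0L, 0L))
  A <- plant_matrix()
  expect_equal(step_population(c(100, 50, 50), A, K = Inf, rounding = "none"),
               as.vector(A %*% c(100, 50, 50)))
})

test_that("replicate runs are deterministic under the config seed", {
  A <- plant_matrix()
  pops <- list(list(patch_id = 1L, N = c(50L, 25L, 25L), K = 500L),
               list(patch_id = 2L, N = c(100L, 50L, 50L), K = 1000L))
  cfg <- sim_config(A, n_replicates = 20, horizon_years = 10, seed = 5)
  r1 <- run_replicates(pops, cfg)
  r2 <- run_replicates(pops, cfg)
  expect_identical(r1$totals, r2$totals)
  cfg2 <- sim_config(A, n_replicates = 20, horizon_years = 10, seed = 6)
  expect_false(identical(run_replicates(pops, cfg2)$totals, r1$totals))
  expect_true(all(r1$totals >= 0))
})

test_that("scheduled K updates cap the metapopulation from the update year", {
  A <- plant_matrix()  # lambda > 1: presses against the ceiling
  pops <- list(list(patch_id = 1L, N = c(500L, 250L, 250L), K = 1000L))
  cfg <- sim_config(A, stochasticity = stochasticity_spec(0, 0),
                    n_replicates = 1, horizon_years = 10,
                    k_schedule = list(years = 5, K = matrix(100, 1, 1)),
                    rounding = "round", seed = 1)
  r <- run_replicates(pops, cfg)
  expect_true(all(r$totals[1, 7:11] <= 100))
  expect_gt(r$totals[1, 5], 100)
})

test_that("summaries report percent-of-initial quantiles and extinction risk", {
  A <- plant_matrix()
  pops <- list(list(patch_id = 1L, N = c(100L, 50L, 50L), K = 2000L))
  cfg <- sim_config(A, n_replicates = 40, horizon_years = 8, seed = 2)
  r <- run_replicates(pops, cfg)
  s <- summarize_result(r)
  expect_equal(s$by_year$q50[1], 100)
  expect_true(all(s$by_year$q2.5 <= s$by_year$q50 & s$by_year$q50 <= s$by_year$q97.5))
  expect_true(all(diff(s$by_year$qe_prob) >= 0))
  # relative to itself: zero change everywhere
  s0 <- summarize_result(r, r)
  expect_true(all(abs(s0$by_year$rel_change) < 1e-12))
  # quantiles match a nearest-rank sorting oracle
  pct <- r$totals / r$initial_total * 100
  for (y in c(1, 5, 9)) {
    srt <- sort(pct[, y])
    expect_equal(s$by_year$q2.5[y], srt[ceiling(0.025 * 40)])
    expect_equal(s$by_year$q50[y], srt[ceiling(0.5 * 40)])
    expect_equal(s$by_year$q97.5[y], srt[ceiling(0.975 * 40)])
  }
  # all replicates extinct: risk 1 from the extinction year on
  dead <- sim_config(matrix(0, 3, 3), stochasticity = stochasticity_spec(0, 0),
                     n_replicates = 5, horizon_years = 4, seed = 3)
  rd <- run_replicates(pops, dead)
  sd_ <- summarize_result(rd)
  expect_equal(sd_$by_year$qe_prob[-1], rep(1, 4))
})

test_that("interaction classification follows the combined-vs-sum rule", {
  expect_equal(classify_interaction(-10, -20, -30)$classification, "additive")
  expect_equal(classify_interaction(-10, -20, -40)$classification, "synergistic")
  expect_equal(classify_interaction(-10, -20, -22)$classification, "antagonistic")
  wide <- classify_interaction(-10, -20, -25,
                               interval_sum = c(-45, -15),
                               interval_combined = c(-40, -10))
  expect_equal(wide$classification, "indeterminate")
  tight <- classify_interaction(-10, -20, -25,
                                interval_sum = c(-31, -29),
                                interval_combined = c(-26, -24))
  expect_equal(tight$classification, "antagonistic")
})
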