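# Replicated stochastic projection of the metapopulation: environmental
# stochasticity on vital rates, ceiling density dependence, scheduled
# carrying-capacity updates, harvest rules, and result summarization.

#' Environmental stochasticity specification
#'
#' Year-to-year multiplicative variation of vital rates: lognormal deviates
#' with mean 1 and the given coefficients of variation (defaults 20% for
#' reproduction, 10% for survival/transitions). To limit truncation at high
#' survival, the deviate of each stage's largest survival rate is negatively
#' correlated with the deviates of that stage's other survival rates.
#'
#' @param cv_fecundity CV of reproduction deviates (>= 0), default 0.20.
#' @param cv_transitions CV of survival/transition deviates (>= 0),
#'   default 0.10.
#' @param survival_correlation construction correlation (<= 0) between the
#'   largest survival deviate and the others within a stage; default -0.7.
#' @return object of class `pva_stochasticity`.
#' @export
stochasticity_spec <- function(cv_fecundity = 0.20, cv_transitions = 0.10,
                               survival_correlation = -0.7) {
  if (cv_fecundity < 0 || cv_transitions < 0)
    stop("stochasticity_spec(): CVs must be >= 0")
  if (survival_correlation > 0)
    stop("stochasticity_spec(): survival_correlation must be <= 0")
  structure(list(cv_fecundity = cv_fecundity, cv_transitions = cv_transitions,
                 survival_correlation = survival_correlation),
            class = "pva_stochasticity")
}

#' Harvest rule specification
#'
#' A fixed quota removed from each population at a fixed interval, with a
#' minimum population size below which a population is never harvested
#' (small populations are assumed harder to locate). `"JUV"` removes only
#' juveniles; `"ALL"` removes the quota from all stages combined,
#' apportioned proportionally to stage abundance.
#'
#' @param strategy `"NONE"`, `"JUV"`, or `"ALL"`.
#' @param quota individuals removed per population per event (default 5).
#' @param interval years between events (default 2: every second year, to
#'   allow some recovery time).
#' @param min_population harvest only populations at or above this total
#'   (default 50).
#' @return object of class `pva_harvest`.
#' @export
harvest_spec <- function(strategy = c("NONE", "JUV", "ALL"), quota = 5,
                         interval = 2, min_population = 50) {
  strategy <- match.arg(strategy)
  if (quota < 0 || interval < 1 || min_population < 0)
    stop("harvest_spec(): quota >= 0, interval >= 1, min_population >= 0 required")
  structure(list(strategy = strategy, quota = as.integer(quota),
                 interval = as.integer(interval),
                 min_population = as.integer(min_population)),
            class = "pva_harvest")
}

# scale survival multipliers per column so effective survival sums stay <= 1
truncate_survival <- function(A_eff) {
  sm <- survival_mask()
  for (j in 1:3) {
    s <- sum(A_eff[sm[, j], j])
    if (s > 1) A_eff[sm[, j], j] <- A_eff[sm[, j], j] / s
  }
  A_eff
}

#' Draw one year of environmental vital-rate multipliers
#'
#' Lognormal mean-1 deviates per nonzero matrix entry: reproduction entries
#' at `cv_fecundity`, survival/transition entries at `cv_transitions`. The
#' deviate applied to each stage's largest survival entry is anticorrelated
#' with the deviates of that stage's other survival entries
#' (`survival_correlation` on the underlying normals). The returned
#' multipliers are already truncated so that the effective per-stage
#' survival sums of `matrix x multipliers` do not exceed 1. With zero CVs
#' every multiplier is exactly 1.
#'
#' @param matrix the 3x3 stage matrix the multipliers will be applied to.
#' @param spec a [stochasticity_spec()].
#' @param seed optional integer seed; `NULL` (the default) draws from the
#'   current RNG stream, as the replicate simulator requires.
#' @return 3x3 multiplier matrix (1 at structurally zero entries).
#' @export
draw_env_multipliers <- function(matrix, spec = stochasticity_spec(), seed = NULL) {
  draw <- function() {
    mult <- base::matrix(1, 3, 3)
    sm <- survival_mask()
    rho <- spec$survival_correlation
    if (spec$cv_transitions > 0) {
      sig <- sqrt(log(1 + spec$cv_transitions^2))
      for (j in 1:3) {
        idx <- which(sm[, j] & matrix[, j] > 0)
        if (length(idx) == 0) next
        big <- idx[which.max(matrix[idx, j])]
        z_big <- stats::rnorm(1)
        z <- stats::setNames(numeric(length(idx)), idx)
        z[as.character(big)] <- z_big
        others <- setdiff(idx, big)
        if (length(others) > 0)
          z[as.character(others)] <- rho * z_big +
            sqrt(1 - rho^2) * stats::rnorm(length(others))
        mult[idx, j] <- exp(-sig^2 / 2 + sig * z[as.character(idx)])
      }
    }
    if (spec$cv_fecundity > 0) {
      sigf <- sqrt(log(1 + spec$cv_fecundity^2))
      for (j in 2:3) if (matrix[1, j] > 0)
        mult[1, j] <- exp(-sigf^2 / 2 + sigf * stats::rnorm(1))
    }
    eff <- truncate_survival(matrix * mult)
    out <- ifelse(matrix > 0, eff / ifelse(matrix > 0, matrix, 1), 1)
    dimnames(out) <- NULL
    out
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Ceiling density dependence
#'
#' If total abundance exceeds the carrying capacity, all stages are scaled
#' down proportionally (largest-remainder integer rounding) so the new total
#' equals K exactly; otherwise the state is unchanged.
#'
#' @param N integer abundances per stage.
#' @param K carrying capacity (>= 0).
#' @return integer abundances with `sum(N) <= K` guaranteed.
#' @export
apply_ceiling <- function(N, K) {
  if (K < 0) stop("apply_ceiling(): K must be >= 0")
  if (!is.finite(K) || sum(N) <= K) return(as.integer(N))
  if (K == 0) return(integer(length(N)))
  largest_remainder(N, K)
}

#' Apply the harvest rule to one population in one year
#'
#' No removal in non-harvest years (`year %% interval != 0`) or when the
#' total abundance is below the minimum population size. `"JUV"` removes
#' `min(quota, juveniles)` juveniles; `"ALL"` removes the quota apportioned
#' across stages proportionally to abundance (largest-remainder rounding,
#' ties broken juvenile, then subadult, then adult), capped by availability.
#'
#' @param N integer abundances (juvenile, subadult, adult).
#' @param spec a [harvest_spec()].
#' @param year simulation year (1-based; events fire when divisible by the
#'   interval).
#' @return list with `N` (post-harvest) and `harvested` (total removed).
#' @export
harvest_population <- function(N, spec, year) {
  N <- as.integer(N)
  if (spec$strategy == "NONE" || spec$quota == 0 ||
      year %% spec$interval != 0 || sum(N) < spec$min_population)
    return(list(N = N, harvested = 0L))
  if (spec$strategy == "JUV") {
    take <- min(spec$quota, N[1])
    N[1] <- N[1] - take
    return(list(N = N, harvested = as.integer(take)))
  }
  # ALL: proportional apportionment capped by availability
  q <- min(spec$quota, sum(N))
  take <- largest_remainder(N, q)
  over <- pmax(take - N, 0L)
  if (any(over > 0)) {         # redistribute any overshoot in stage order
    take <- pmin(take, N)
    short <- q - sum(take)
    for (s in 1:3) {
      add <- min(short, N[s] - take[s])
      take[s] <- take[s] + add; short <- short - add
      if (short == 0) break
    }
  }
  list(N = as.integer(N - take), harvested = as.integer(sum(take)))
}

#' Project one population one year forward
#'
#' Applies the effective matrix (stage matrix times environmental
#' multipliers, survival sums truncated at 1) to the abundance vector, then
#' the ceiling rule at K. By default the expected abundances are converted
#' to integers by unbiased stochastic rounding; `rounding = "round"` rounds
#' deterministically and `rounding = "none"` keeps real-valued abundances
#' (the deterministic limit). Optional demographic stochasticity replaces
#' the expectation with binomial stage fates and Poisson recruitment.
#'
#' @param N abundances per stage.
#' @param matrix 3x3 stage matrix.
#' @param multipliers 3x3 environmental multipliers (default all 1).
#' @param K carrying capacity (default `Inf`).
#' @param rounding `"stochastic"`, `"round"`, or `"none"`.
#' @param demographic logical; draw binomial/Poisson demographic noise.
#' @return the new abundance vector.
#' @export
step_population <- function(N, matrix, multipliers = NULL, K = Inf,
                            rounding = c("stochastic", "round", "none"),
                            demographic = FALSE) {
  rounding <- match.arg(rounding)
  eff <- if (is.null(multipliers)) matrix else truncate_survival(matrix * multipliers)
  if (demographic) {
    sm <- survival_mask()
    Nn <- numeric(3)
    for (j in 1:3) {
      nj <- round(N[j])
      if (nj <= 0) next
      p <- eff[sm[, j], j]
      fates <- stats::rmultinom(1, nj, c(p, max(0, 1 - sum(p))))[, 1]
      Nn[which(sm[, j])] <- Nn[which(sm[, j])] + fates[seq_along(p)]
      if (j >= 2 && eff[1, j] > 0)
        Nn[1] <- Nn[1] + stats::rpois(1, eff[1, j] * nj)
    }
  } else {
    Nn <- as.vector(eff %*% N)
    Nn <- switch(rounding,
                 stochastic = stochastic_round(Nn),
                 round = round(Nn),
                 none = Nn)
  }
  if (rounding == "none" && !demographic) {
    tot <- sum(Nn)
    if (is.finite(K) && tot > K) Nn <- Nn * K / tot
    return(Nn)
  }
  as.integer(apply_ceiling(as.integer(Nn), K))
}

#' Simulation configuration
#'
#' @param matrix 3x3 stage matrix driving all populations.
#' @param stochasticity a [stochasticity_spec()].
#' @param harvest a [harvest_spec()].
#' @param n_replicates number of stochastic replicates (>= 1).
#' @param horizon_years simulation length (>= 1), default 30.
#' @param k_schedule optional carrying-capacity schedule: list with `years`
#'   (simulation years at which K changes, e.g. `c(5, 10, ...)`) and `K` (a
#'   matrix, one row per schedule year, one column per population).
#' @param quasi_extinction_threshold metapopulation total below which a
#'   replicate counts as quasi-extinct (default 10).
#' @param rounding abundance rounding rule, see [step_population()].
#' @param demographic logical; demographic stochasticity (default off).
#' @param seed integer root seed; replicate `r` draws from substream
#'   (`seed`, r).
#' @return object of class `pva_sim_config`.
#' @export
sim_config <- function(matrix, stochasticity = stochasticity_spec(),
                       harvest = harvest_spec("NONE"), n_replicates = 100,
                       horizon_years = 30, k_schedule = NULL,
                       quasi_extinction_threshold = 10,
                       rounding = "stochastic", demographic = FALSE, seed = 1) {
  if (n_replicates < 1 || horizon_years < 1)
    stop("sim_config(): n_replicates and horizon_years must be >= 1")
  if (!is.null(k_schedule)) {
    stopifnot(is.list(k_schedule), !is.null(k_schedule$years), !is.null(k_schedule$K))
    k_schedule$K <- as.matrix(k_schedule$K)
    if (nrow(k_schedule$K) != length(k_schedule$years))
      stop("sim_config(): k_schedule$K needs one row per schedule year")
  }
  structure(list(matrix = leslie_matrix(matrix), stochasticity = stochasticity,
                 harvest = harvest, n_replicates = as.integer(n_replicates),
                 horizon_years = as.integer(horizon_years),
                 k_schedule = k_schedule,
                 quasi_extinction_threshold = quasi_extinction_threshold,
                 rounding = rounding, demographic = demographic,
                 seed = as.integer(seed)),
            class = "pva_sim_config")
}

#' Run replicated stochastic projections of a metapopulation
#'
#' For each replicate: populations start at their initial abundances (stable
#' stage distribution at initialization); each year, carrying capacities are
#' updated if scheduled, every population draws its own environmental
#' multipliers and is projected with ceiling density dependence, and the
#' harvest rule is applied. Fully deterministic given the config seed.
#'
#' @param metapopulation list of population states from
#'   [initialize_population()] (fields `N`, `K`).
#' @param config a [sim_config()].
#' @return object of class `pva_sim_result`: `totals` (replicates x years
#'   0..horizon matrix of metapopulation totals), `stage_totals` (replicates
#'   x years x 3), `harvest_log` (data.frame of per-event audits: replicate,
#'   year, population, pre-harvest total, juveniles, taken),
#'   `initial_total`, and the `config`.
#' @export
run_replicates <- function(metapopulation, config) {
  stopifnot(inherits(config, "pva_sim_config"), length(metapopulation) >= 1)
  npop <- length(metapopulation)
  h <- config$horizon_years
  R <- config$n_replicates
  totals <- matrix(0, R, h + 1)
  stage_totals <- array(0, c(R, h + 1, 3))
  audit <- config$harvest$strategy != "NONE"
  log_rep <- integer(0); log_year <- integer(0); log_pop <- integer(0)
  log_pre <- integer(0); log_juv <- integer(0); log_taken <- integer(0)
  N0 <- vapply(metapopulation, function(p) as.numeric(p$N), numeric(3))
  K0 <- vapply(metapopulation, function(p) as.numeric(p$K), numeric(1))
  sched <- config$k_schedule
  for (r in seq_len(R)) {
    res <- with_seed(derive_seed(config$seed, "rep", r), {
      N <- N0; K <- K0
      tot <- numeric(h + 1); st <- matrix(0, h + 1, 3)
      tot[1] <- sum(N); st[1, ] <- rowSums(N)
      for (y in seq_len(h)) {
        if (!is.null(sched)) {
          hit <- which(sched$years == y)
          if (length(hit) == 1) K <- as.numeric(sched$K[hit, ])
        }
        for (p in seq_len(npop)) {
          mult <- draw_env_multipliers(config$matrix, config$stochasticity)
          N[, p] <- step_population(N[, p], config$matrix, mult, K[p],
                                    rounding = config$rounding,
                                    demographic = config$demographic)
          if (audit && y %% config$harvest$interval == 0) {
            pre <- sum(N[, p]); juv <- N[1, p]
            hv <- harvest_population(N[, p], config$harvest, y)
            N[, p] <- hv$N
            log_rep <- c(log_rep, r); log_year <- c(log_year, y)
            log_pop <- c(log_pop, p); log_pre <- c(log_pre, as.integer(pre))
            log_juv <- c(log_juv, as.integer(juv))
            log_taken <- c(log_taken, hv$harvested)
          }
        }
        tot[y + 1] <- sum(N); st[y + 1, ] <- rowSums(N)
      }
      list(tot = tot, st = st)
    })
    totals[r, ] <- res$tot
    stage_totals[r, , ] <- res$st
  }
  structure(list(
    totals = totals, stage_totals = stage_totals,
    harvest_log = data.frame(replicate = log_rep, year = log_year,
                             population = log_pop, pre_total = log_pre,
                             juveniles = log_juv, taken = log_taken),
    initial_total = sum(N0), config = config),
    class = "pva_sim_result")
}

#' @export
print.pva_sim_result <- function(x, ...) {
  cat(sprintf("<pva_sim_result> %d replicates x %d years, initial total %d\n",
              nrow(x$totals), ncol(x$totals) - 1, as.integer(x$initial_total)))
  invisible(x)
}

#' Summarize replicate trajectories
#'
#' Per-year nearest-rank percentiles (2.5/50/97.5 by default) of total
#' abundance as a percentage of initial conditions, cumulative
#' quasi-extinction probability, harvest totals, and — when a baseline
#' result is supplied — the per-year change of the median percentage
#' relative to the baseline's (percentage points), with an interval from the
#' scenario's replicate percentiles.
#'
#' @param result a `pva_sim_result`.
#' @param baseline_result optional `pva_sim_result` on the same horizon.
#' @param probs percentile levels, default `c(0.025, 0.5, 0.975)`.
#' @return object of class `pva_summary`: data.frame `by_year` (year, the
#'   percentile columns in percent of initial, `qe_prob`, and relative-change
#'   columns when a baseline is given), plus `harvest_total` (median across
#'   replicates).
#' @export
summarize_result <- function(result, baseline_result = NULL,
                             probs = c(0.025, 0.5, 0.975)) {
  pct <- result$totals / result$initial_total * 100
  yrs <- 0:(ncol(pct) - 1)
  qs <- t(apply(pct, 2, nearest_rank_quantile, probs = probs))
  colnames(qs) <- paste0("q", probs * 100)
  below <- result$totals < result$config$quasi_extinction_threshold
  qe <- colMeans(t(apply(below, 1, cummax)) >= 1)
  by_year <- data.frame(year = yrs, qs, qe_prob = qe, check.names = FALSE)
  if (!is.null(baseline_result)) {
    if (ncol(baseline_result$totals) != ncol(result$totals))
      stop("summarize_result(): results must share the horizon")
    bpct <- baseline_result$totals / baseline_result$initial_total * 100
    bmed <- apply(bpct, 2, nearest_rank_quantile, probs = 0.5)
    by_year$rel_change <- by_year$q50 - bmed
    rel_lo <- t(apply(pct, 2, nearest_rank_quantile, probs = min(probs))) - bmed
    rel_hi <- t(apply(pct, 2, nearest_rank_quantile, probs = max(probs))) - bmed
    by_year$rel_lo <- as.numeric(rel_lo)
    by_year$rel_hi <- as.numeric(rel_hi)
  }
  ht <- if (nrow(result$harvest_log) > 0) {
    per_rep <- tapply(result$harvest_log$taken, result$harvest_log$replicate, sum)
    stats::median(per_rep)
  } else 0
  structure(list(by_year = by_year, harvest_total = ht), class = "pva_summary")
}

#' @export
print.pva_summary <- function(x, ...) {
  cat("<pva_summary>\n")
  print(utils::head(x$by_year, 3))
  cat("...\n")
  print(utils::tail(x$by_year, 1))
  invisible(x)
}

#' Classify the interaction between combined pressures
#'
#' Compares the magnitude of the combined effect to the magnitude of the sum
#' of the individual effects (signed relative changes, declines negative):
#' larger means synergistic, equal (within `tolerance`) additive, smaller
#' antagonistic. Whenever the uncertainty interval of the combined effect
#' overlaps the interval of the sum, the classification is indeterminate —
#' the uncertainty is too large to identify the interaction type.
#'
#' @param effect_cc,effect_lc,effect_combined signed effect sizes
#'   (percentage-point changes relative to baseline).
#' @param interval_sum,interval_combined optional length-2 uncertainty
#'   intervals for the sum of individual effects and the combined effect.
#' @param tolerance additivity tolerance in the effect units (default 1
#'   percentage point).
#' @return list with `classification` (`"synergistic"`, `"additive"`,
#'   `"antagonistic"`, or `"indeterminate"`), `effect_sum`,
#'   `effect_combined`, and `difference` (|combined| - |sum|).
#' @export
classify_interaction <- function(effect_cc, effect_lc, effect_combined,
                                 interval_sum = NULL, interval_combined = NULL,
                                 tolerance = 1) {
  effect_sum <- effect_cc + effect_lc
  diff <- abs(effect_combined) - abs(effect_sum)
  cls <- if (!is.null(interval_sum) && !is.null(interval_combined) &&
             interval_combined[1] <= interval_sum[2] &&
             interval_sum[1] <= interval_combined[2]) {
    "indeterminate"
  } else if (abs(diff) < tolerance) {
    "additive"
  } else if (diff > 0) {
    "synergistic"
  } else {
    "antagonistic"
  }
  list(classification = cls, effect_sum = effect_sum,
       effect_combined = effect_combined, difference = diff)
}
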