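# Three-stage (juvenile, subadult, adult) matrix demography: constrained
# error minimization of vital rates from stage-count census tables,
# bootstrap matrix pools, and eigen-quantities.

STAGES <- c("juvenile", "subadult", "adult")

# Survival/transition entries of the 3x3 stage matrix: everything except the
# reproduction entries in the juvenile row, columns 2:3 (sexual + clonal
# recruits are pooled there). Survival column sums exclude reproduction.
survival_mask <- function() {
  m <- matrix(TRUE, 3, 3)
  m[1, 2:3] <- FALSE
  m
}

# names of the free rates, in the order used by the fitter
RATE_NAMES <- c("s11", "s21", "s31", "s22", "s32", "s23", "s33", "f2", "f3")

rates_to_matrix <- function(theta) {
  A <- matrix(0, 3, 3, dimnames = list(STAGES, STAGES))
  A[1, 1] <- theta[1]; A[2, 1] <- theta[2]; A[3, 1] <- theta[3]
  A[2, 2] <- theta[4]; A[3, 2] <- theta[5]
  A[2, 3] <- theta[6]; A[3, 3] <- theta[7]
  A[1, 2] <- theta[8]; A[1, 3] <- theta[9]
  A
}

matrix_to_rates <- function(A) {
  c(A[1, 1], A[2, 1], A[3, 1], A[2, 2], A[3, 2], A[2, 3], A[3, 3], A[1, 2], A[1, 3])
}

# per-column survival sums (reproduction excluded)
column_survival_sums <- function(A) {
  sm <- survival_mask()
  colSums(A * sm)
}

#' Construct and validate a three-stage projection matrix
#'
#' Columns give the fate of each stage; the juvenile row of columns 2:3
#' carries per-capita reproduction (sexual plus clonal recruits). Entries
#' must be nonnegative and each stage's total survival (column sum excluding
#' reproduction) must not exceed 1.
#'
#' @param A numeric 3x3 matrix.
#' @return `A` with stage dimnames, validated.
#' @export
leslie_matrix <- function(A) {
  A <- as.matrix(A)
  if (!all(dim(A) == c(3, 3))) stop("leslie_matrix(): matrix must be 3x3")
  if (any(A < 0)) stop("leslie_matrix(): entries must be nonnegative")
  cs <- column_survival_sums(A)
  if (any(cs > 1 + 1e-9))
    stop("leslie_matrix(): per-stage survival (column sum excluding reproduction) exceeds 1")
  dimnames(A) <- list(STAGES, STAGES)
  A
}

#' Dominant eigenvalue of a projection matrix
#'
#' Spectral radius; for a nonnegative matrix this is the asymptotic growth
#' rate lambda (Perron root).
#'
#' @param A square numeric matrix.
#' @return lambda (numeric scalar).
#' @export
dominant_eigenvalue <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("dominant_eigenvalue(): matrix must be square")
  ev <- eigen(A, only.values = TRUE)$values
  max(Mod(ev))
}

# is the nonnegative matrix irreducible? (strong connectivity of its graph)
is_irreducible <- function(A) {
  n <- nrow(A)
  B <- (abs(A) > 0) * 1
  R <- diag(n) + B
  P <- R
  for (k in seq_len(n - 1)) P <- P %*% R
  all(P > 0)
}

#' Stable stage distribution
#'
#' Normalized dominant right eigenvector of the stage matrix: the asymptotic
#' proportion of individuals per stage. For reducible matrices (e.g. the
#' identity), where the dominant eigenvector is not unique, the documented
#' fallback is the uniform distribution.
#'
#' @param A square nonnegative matrix.
#' @return numeric vector of stage proportions summing to 1.
#' @export
stable_stage_distribution <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (!is_irreducible(A)) return(rep(1 / n, n))
  e <- eigen(A)
  # Perron root: among modulus-maximal eigenvalues (several for periodic
  # matrices), the real positive one
  cand <- which(Mod(e$values) >= max(Mod(e$values)) - 1e-10)
  i <- cand[which.max(Re(e$values[cand]))]
  v <- Re(e$vectors[, i])
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  v / sum(v)
}

# ---- stage-count table handling --------------------------------------------

TRANS_COLS <- c("t_jj", "t_js", "t_ja", "t_ss", "t_sa", "t_as", "t_aa")
REC_COLS <- c("rec_sub", "rec_adult")
COUNT_COLS <- c("n_juv", "n_sub", "n_adult")

# Split a stage-count table into per-transition-year blocks, each holding the
# source counts, destination counts, and recorded transition/recruit counts.
table_to_blocks <- function(tab) {
  need <- c("year", COUNT_COLS)
  if (!all(need %in% names(tab)))
    stop("stage-count table must have columns: ", paste(need, collapse = ", "))
  tab <- tab[order(tab$year), , drop = FALSE]
  Nc <- t(as.matrix(tab[, COUNT_COLS]))
  if (any(is.na(Nc)) || any(Nc < 0))
    stop("stage-count table is infeasible: counts must be nonnegative and complete")
  if (ncol(Nc) < 2) stop("stage-count table needs at least 2 census years")
  if (any(rowSums(Nc) == 0))
    stop("stage-count table has an all-zero stage; rates for it are unidentifiable")
  has_trans <- all(c(TRANS_COLS, REC_COLS) %in% names(tab))
  blocks <- vector("list", ncol(Nc) - 1)
  for (t in seq_len(ncol(Nc) - 1)) {
    b <- list(n_from = Nc[, t], n_to = Nc[, t + 1], trans = NULL, rec = NULL)
    if (has_trans && !any(is.na(tab[t, c(TRANS_COLS, REC_COLS)]))) {
      b$trans <- as.numeric(tab[t, TRANS_COLS]); names(b$trans) <- TRANS_COLS
      b$rec <- as.numeric(tab[t, REC_COLS]); names(b$rec) <- REC_COLS
    }
    blocks[[t]] <- b
  }
  blocks
}

# map from transition-column name to (row, col) of the stage matrix
TRANS_INDEX <- cbind(
  row = c(1, 2, 3, 2, 3, 2, 3),
  col = c(1, 1, 1, 2, 2, 3, 3))

# least-squares objective over blocks; returns function(theta) -> value
make_objective <- function(blocks, penalty = 1e6) {
  function(theta) {
    A <- rates_to_matrix(theta)
    val <- 0
    for (b in blocks) {
      pred <- as.vector(A %*% b$n_from)
      val <- val + sum((b$n_to - pred)^2)
      if (!is.null(b$trans)) {
        for (k in seq_along(TRANS_COLS)) {
          a <- A[TRANS_INDEX[k, 1], TRANS_INDEX[k, 2]]
          val <- val + (b$trans[k] - a * b$n_from[TRANS_INDEX[k, 2]])^2
        }
        val <- val + (b$rec[1] - theta[8] * b$n_from[2])^2 +
          (b$rec[2] - theta[9] * b$n_from[3])^2
      }
    }
    cs <- column_survival_sums(A)
    val + penalty * sum(pmax(cs - 1, 0)^2)
  }
}

# direct per-entry least-squares start values from recorded transition counts
# (falling back to small positive defaults when a block lacks them)
start_rates <- function(blocks) {
  theta <- rep(0.1, 9)
  num <- rep(0, 9); den <- rep(0, 9)
  for (b in blocks) {
    if (is.null(b$trans)) next
    for (k in seq_along(TRANS_COLS)) {
      nf <- b$n_from[TRANS_INDEX[k, 2]]
      num[k] <- num[k] + b$trans[k] * nf
      den[k] <- den[k] + nf^2
    }
    num[8] <- num[8] + b$rec[1] * b$n_from[2]; den[8] <- den[8] + b$n_from[2]^2
    num[9] <- num[9] + b$rec[2] * b$n_from[3]; den[9] <- den[9] + b$n_from[3]^2
  }
  est <- ifelse(den > 0, num / den, NA_real_)
  theta[!is.na(est)] <- est[!is.na(est)]
  # keep start feasible for the survival-sum constraints
  A <- rates_to_matrix(theta)
  cs <- column_survival_sums(A)
  for (j in 1:3) if (cs[j] > 1) {
    sm <- survival_mask()[, j]
    A[sm, j] <- A[sm, j] / cs[j] * 0.999
  }
  matrix_to_rates(A)
}

fit_rates <- function(blocks) {
  obj <- make_objective(blocks)
  theta0 <- start_rates(blocks)
  if (obj(theta0) < 1e-18) {
    theta <- theta0  # exact (noise-free) table: the direct estimates solve it
  } else {
    upper <- c(rep(1, 7), Inf, Inf)
    fit <- stats::nlminb(theta0, obj, lower = rep(0, 9), upper = upper,
                         control = list(iter.max = 500, eval.max = 1000,
                                        rel.tol = 1e-14))
    theta <- fit$par
  }
  A <- rates_to_matrix(theta)
  cs <- column_survival_sums(A)
  for (j in 1:3) if (cs[j] > 1) {  # numeric safety projection
    sm <- survival_mask()[, j]
    A[sm, j] <- A[sm, j] / cs[j]
  }
  list(matrix = leslie_matrix(A), rates = matrix_to_rates(A),
       residual = make_objective(blocks, penalty = 0)(matrix_to_rates(A)),
       lambda = dominant_eigenvalue(A))
}

#' Derive consistent vital rates from a stage-count census table
#'
#' Census tables of stage counts, stage-to-stage transition counts, recruits,
#' and deaths are typically internally inconsistent (transitions need not sum
#' to next-year counts). This resolves them by constrained least squares:
#' rates minimizing the summed squared discrepancies between (a) observed
#' year-to-year stage counts and those implied by the rates and (b) observed
#' per-entry transition/recruit counts and their rate-implied expectations,
#' subject to nonnegativity and per-stage survival sums at most 1.
#'
#' @param stage_count_table data.frame with columns `year`, `n_juv`, `n_sub`,
#'   `n_adult` and optionally the transition columns `t_jj, t_js, t_ja, t_ss,
#'   t_sa, t_as, t_aa` (from-to counts), `rec_sub`, `rec_adult` (new
#'   juveniles by parent stage), as produced by [gen_stage_counts()].
#' @return list with `matrix` (the fitted [leslie_matrix()]), `rates` (the 9
#'   free rates), `residual` (objective at the optimum), and `lambda`.
#' @export
error_minimize <- function(stage_count_table) {
  fit_rates(table_to_blocks(stage_count_table))
}

#' Build a pool of stage matrices by bootstrap over census years
#'
#' Captures parameter uncertainty in the vital rates: the first pool member
#' is the point estimate from the full table; further members refit the
#' rates on transition-years resampled with replacement (nonparametric
#' bootstrap).
#'
#' @param stage_count_table see [error_minimize()].
#' @param n_resamples pool size (>= 1).
#' @param seed integer seed.
#' @param site optional site label carried as provenance.
#' @return object of class `pva_matrix_pool`: list with `matrices` (list of
#'   3x3 matrices), `lambda` (numeric vector), `resample` (0 for the point
#'   estimate), `site`.
#' @export
build_matrix_pool <- function(stage_count_table, n_resamples, seed = 1, site = NULL) {
  if (n_resamples < 1) stop("build_matrix_pool(): n_resamples must be >= 1")
  blocks <- table_to_blocks(stage_count_table)
  mats <- vector("list", n_resamples)
  mats[[1]] <- fit_rates(blocks)$matrix
  if (n_resamples > 1) {
    with_seed(derive_seed(seed, "pool"), {
      for (r in 2:n_resamples) {
        idx <- sample.int(length(blocks), length(blocks), replace = TRUE)
        mats[[r]] <- fit_rates(blocks[idx])$matrix
      }
    })
  }
  structure(list(
    matrices = mats,
    lambda = vapply(mats, dominant_eigenvalue, numeric(1)),
    resample = seq_len(n_resamples) - 1L,
    site = site),
    class = "pva_matrix_pool")
}

#' @export
print.pva_matrix_pool <- function(x, ...) {
  cat(sprintf("<pva_matrix_pool> %d matrices%s, lambda in [%.3f, %.3f]\n",
              length(x$matrices),
              if (is.null(x$site)) "" else paste0(" (site ", x$site, ")"),
              min(x$lambda), max(x$lambda)))
  invisible(x)
}

#' Select percentile matrices from a pool by dominant eigenvalue
#'
#' Sorts the pool by lambda (ties broken by resample id) and returns the
#' members at the nearest-rank percentiles, so every selected matrix is an
#' actual pool member.
#'
#' @param pool a `pva_matrix_pool`.
#' @param percentiles numeric percentiles in \[0, 100\]; default
#'   `c(2.5, 50, 97.5)`.
#' @return named list of matrices (names like "p2.5"), each with attributes
#'   `lambda` and `resample`.
#' @export
select_percentile_matrices <- function(pool, percentiles = c(2.5, 50, 97.5)) {
  if (length(pool$matrices) == 0) stop("select_percentile_matrices(): empty pool")
  ord <- order(pool$lambda, pool$resample)
  n <- length(ord)
  out <- list()
  for (p in percentiles) {
    k <- min(max(ceiling(p / 100 * n), 1L), n)
    i <- ord[k]
    m <- pool$matrices[[i]]
    attr(m, "lambda") <- pool$lambda[i]
    attr(m, "resample") <- pool$resample[i]
    out[[paste0("p", format(p))]] <- m
  }
  out
}
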