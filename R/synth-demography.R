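# Synthetic stage-structured census data generated from a known projection
# matrix, for testing the demographic rate-fitting machinery end to end.

#' Ground truth for synthetic demographic data
#'
#' @param matrix a 3x3 stage matrix (validated by [leslie_matrix()]).
#' @param years number of census years (>= 2).
#' @param initial_counts nonnegative counts per stage (juvenile, subadult,
#'   adult) in census year 1.
#' @param observation_noise_cv coefficient of variation of multiplicative
#'   lognormal observation noise applied to every recorded count (0 = exact).
#' @return object of class `pva_demography_truth`.
#' @export
demography_truth <- function(matrix, years, initial_counts,
                             observation_noise_cv = 0) {
  matrix <- leslie_matrix(matrix)
  if (years < 2) stop("demography_truth(): years must be >= 2")
  if (length(initial_counts) != 3 || any(initial_counts < 0))
    stop("demography_truth(): initial_counts must be 3 nonnegative values")
  if (observation_noise_cv < 0)
    stop("demography_truth(): observation_noise_cv must be >= 0")
  structure(list(matrix = matrix, years = as.integer(years),
                 initial_counts = as.numeric(initial_counts),
                 observation_noise_cv = observation_noise_cv),
            class = "pva_demography_truth")
}

#' Generate a stage-count census table from a known matrix
#'
#' Projects the initial counts through the true matrix and records, per
#' census year: stage counts (`n_juv`, `n_sub`, `n_adult`), stage-to-stage
#' transition counts (`t_jj` juvenile stayed juvenile, `t_js` juvenile to
#' subadult, `t_ja`, `t_ss`, `t_sa`, `t_as` adult regressed to subadult,
#' `t_aa`), new recruits by parent stage (`rec_sub`, `rec_adult`), and
#' per-stage deaths. Transition rows are blank (`NA`) in the final year.
#'
#' Table schema note: with `observation_noise_cv = 0` the recorded values
#' are the exact expected counts (real-valued, not rounded), so the table is
#' exactly consistent with the generating matrix and [error_minimize()]
#' recovers it to numerical precision. With noise, each recorded value is
#' multiplied by an independent lognormal deviate (mean 1, the given CV) and
#' rounded to an integer, as a field census would report.
#'
#' @param truth a [demography_truth()].
#' @param seed integer seed (used only when noise is applied).
#' @return data.frame, one row per census year.
#' @export
gen_stage_counts <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "pva_demography_truth"))
  A <- truth$matrix
  yrs <- truth$years
  N <- truth$initial_counts
  rows <- vector("list", yrs)
  for (t in seq_len(yrs)) {
    row <- list(year = t, n_juv = N[1], n_sub = N[2], n_adult = N[3])
    if (t < yrs) {
      trans <- c(
        t_jj = A[1, 1] * N[1], t_js = A[2, 1] * N[1], t_ja = A[3, 1] * N[1],
        t_ss = A[2, 2] * N[2], t_sa = A[3, 2] * N[2],
        t_as = A[2, 3] * N[3], t_aa = A[3, 3] * N[3])
      rec <- c(rec_sub = A[1, 2] * N[2], rec_adult = A[1, 3] * N[3])
      deaths <- c(
        deaths_juv = N[1] * max(0, 1 - (A[1, 1] + A[2, 1] + A[3, 1])),
        deaths_sub = N[2] * max(0, 1 - (A[2, 2] + A[3, 2])),
        deaths_adult = N[3] * max(0, 1 - (A[2, 3] + A[3, 3])))
      row <- c(row, as.list(trans), as.list(rec), as.list(deaths))
      # next year's counts are the column-wise fates plus recruits
      N <- c(trans["t_jj"] + rec["rec_sub"] + rec["rec_adult"],
             trans["t_js"] + trans["t_ss"] + trans["t_as"],
             trans["t_ja"] + trans["t_sa"] + trans["t_aa"])
      names(N) <- NULL
    } else {
      row <- c(row, stats::setNames(as.list(rep(NA_real_, 12)),
                                    c("t_jj", "t_js", "t_ja", "t_ss", "t_sa",
                                      "t_as", "t_aa", "rec_sub", "rec_adult",
                                      "deaths_juv", "deaths_sub", "deaths_adult")))
    }
    rows[[t]] <- as.data.frame(row)
  }
  tab <- do.call(rbind, rows)
  cv <- truth$observation_noise_cv
  if (cv > 0) {
    sig <- sqrt(log(1 + cv^2))
    with_seed(derive_seed(seed, "counts"), {
      for (cn in setdiff(names(tab), "year")) {
        ok <- !is.na(tab[[cn]])
        noise <- stats::rlnorm(sum(ok), meanlog = -sig^2 / 2, sdlog = sig)
        tab[[cn]][ok] <- round(tab[[cn]][ok] * noise)
      }
    })
  }
  rownames(tab) <- NULL
  tab
}
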