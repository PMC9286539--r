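# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so callers never perturb user-level randomness.
#'
#' @param seed integer seed, or `NULL` to run with the current RNG state.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named substream seed from a root seed
#'
#' Deterministic integer hash so each pipeline stage and replicate draws from
#' its own substream of a single root seed. Result is in [1, 2^31 - 2].
#'
#' @keywords internal
#' @noRd
derive_seed <- function(seed, ...) {
  parts <- c(as.character(seed), vapply(list(...), as.character, character(1)))
  key <- paste(parts, collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483587
  as.integer(h + 1L)
}

#' Largest-remainder integer apportionment
#'
#' Apportions a nonnegative integer `total` across categories proportionally
#' to `weights`: floors the exact shares, then distributes the remaining
#' units by decreasing fractional remainder, ties broken by category order
#' (first category wins).
#'
#' @param weights nonnegative numeric vector; must have a positive sum when
#'   `total > 0`.
#' @param total nonnegative integer to apportion.
#' @return integer vector summing exactly to `total`.
#' @examples
#' largest_remainder(c(60, 40, 20), 100)  # 50 33 17
#' @export
largest_remainder <- function(weights, total) {
  stopifnot(total >= 0, all(weights >= 0))
  total <- as.integer(round(total))
  if (total == 0L) return(integer(length(weights)))
  s <- sum(weights)
  if (s <= 0) stop("largest_remainder(): all weights are zero but total > 0")
  exact <- weights / s * total
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- exact - base
    ord <- order(-frac, seq_along(frac))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Stochastic (unbiased) rounding of a nonnegative numeric vector: floor plus
# a Bernoulli draw on the fractional part. Uses the current RNG state.
stochastic_round <- function(x) {
  f <- floor(x)
  frac <- x - f
  as.integer(f + (stats::runif(length(x)) < frac))
}

# Nearest-rank (type 1) quantile: the smallest value whose empirical CDF
# reaches p. Returned values are always members of `x`.
nearest_rank_quantile <- function(x, probs) {
  s <- sort(x)
  n <- length(s)
  idx <- pmin(pmax(ceiling(probs * n), 1L), n)
  s[idx]
}
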