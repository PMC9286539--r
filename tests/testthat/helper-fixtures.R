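# Shared fixtures, built in code.

# plant-like stage matrix: high stasis, slow maturation, adult reproduction;
# lambda ~ 1.046
plant_matrix <- function() {
  leslie_matrix(rbind(
    c(0.45, 0.05, 0.95),
    c(0.25, 0.70, 0.00),
    c(0.00, 0.20, 0.80)))
}

# low-survival variant (per-stage survival sums 0.5/0.7/0.8) so that
# multiplier truncation at survival-sum 1 essentially never triggers
low_survival_matrix <- function() {
  leslie_matrix(rbind(
    c(0.30, 0.20, 1.50),
    c(0.20, 0.40, 0.00),
    c(0.00, 0.30, 0.50)))
}

# periodic lambda = 1 matrix with known stable stage distribution (2,1,1)/4
cycle_matrix <- function() {
  rbind(c(0, 0, 2), c(0.5, 0, 0), c(0, 1, 0))
}

# brute-force pairwise AUC oracle (independent of the rank-based path)
auc_oracle <- function(p, b) {
  s <- 0
  for (x in p) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(p) * length(b))
}

# brute-force connected components by union-find over all cell pairs
patch_oracle <- function(values, threshold, neighborhood_km, cell_size_km = 1) {
  suit <- which(!is.na(values) & values >= threshold)
  if (length(suit) == 0) return(integer(0))
  d <- dim(values)
  rows <- ((suit - 1) %% d[1]) + 1
  cols <- ((suit - 1) %/% d[1]) + 1
  parent <- seq_along(suit)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(suit)) for (j in seq_len(i - 1)) {
    dist <- sqrt((rows[i] - rows[j])^2 + (cols[i] - cols[j])^2) * cell_size_km
    if (dist <= neighborhood_km) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_along(suit), find, integer(1))
  # canonical labels in scan order
  match(comp, unique(comp[order(suit)]))
}

# deterministic small raster from a matrix
raster_of <- function(m, cell = 1) pva_raster(as.matrix(m), cell_size_km = cell)

# constant monthly climate stacks
constant_months <- function(value, rows = 4, cols = 4, cell = 1) {
  lapply(1:12, function(m) pva_raster(matrix(value, rows, cols), cell))
}
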