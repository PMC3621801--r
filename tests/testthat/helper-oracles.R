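# Independent oracles and small fixtures shared across the test files.

# Three-node toy: O has edges 1-2 and 2-3, T has edge 1-2 (all weights 1).
toy_pair <- function() {
  O <- matrix(0, 3, 3)
  O[1, 2] <- O[2, 1] <- 1
  O[2, 3] <- O[3, 2] <- 1
  T_ <- matrix(0, 3, 3)
  T_[1, 2] <- T_[2, 1] <- 1
  list(O = labeled_network(O, c("g1", "g2", "g3")),
       T = labeled_network(T_, c("g1", "g2", "g3")))
}

# Literal triple-loop evaluation of the defining sums; deliberately slow
# and structured nothing like the package's vectorized implementation.
naive_dissim <- function(WO, WT, edge = TRUE, weight = TRUE,
                         neighbour = "none", cc = 0, tol = 0) {
  n <- nrow(WO)
  ind <- function(w) as.numeric(abs(w) > tol)
  dyad <- function(a, b, j, k) {
    out <- 0
    if (edge) out <- out + abs(ind(a[j, k]) - ind(b[j, k]))
    if (weight) out <- out + abs(a[j, k] - b[j, k])
    out
  }
  total <- 0
  for (i in seq_len(n)) {
    d_i <- 0
    for (j in seq_len(n)) if (j != i) d_i <- d_i + dyad(WO, WT, i, j)
    nbr_i <- 0
    if (neighbour != "none") {
      for (j in seq_len(n)) {
        if (j == i) next
        in_union <- ind(WO[i, j]) > 0 || ind(WT[i, j]) > 0
        c_ij <- switch(neighbour,
                       constant = if (in_union) cc else 0,
                       weighted = WO[i, j] * ind(WT[i, j]),
                       weighted_abs = abs(WO[i, j]) * ind(WT[i, j]))
        if (c_ij == 0) next
        d_star <- 0
        for (k in seq_len(n)) {
          if (k == i || k == j) next
          d_star <- d_star + dyad(WO, WT, j, k)
        }
        nbr_i <- nbr_i + c_ij * d_star
      }
    }
    total <- total + d_i + nbr_i
  }
  total
}

# Symmetric-difference edge count for binary graphs.
sym_diff_edges <- function(WO, WT) {
  up <- upper.tri(WO)
  sum((WO[up] != 0) != (WT[up] != 0))
}

# Random symmetric weight matrix with given edge density.
random_weighted <- function(n, density = 0.4, rng_labels = TRUE) {
  W <- matrix(0, n, n)
  up <- upper.tri(W)
  m <- sum(up)
  w <- ifelse(stats::runif(m) < density, stats::runif(m, -1, 1), 0)
  W[up] <- w
  W <- W + t(W)
  labeled_network(W, labels = paste0("n", seq_len(n)))
}

random_binary <- function(n, p = 0.4) {
  W <- matrix(0, n, n)
  up <- upper.tri(W)
  W[up] <- stats::rbinom(sum(up), 1, p)
  labeled_network(W + t(W), labels = paste0("n", seq_len(n)))
}

# Partial correlation of columns i and j given the rest, via the
# regression-residual definition on raw data.
residual_pcor <- function(X, i, j) {
  rest <- setdiff(seq_len(ncol(X)), c(i, j))
  ri <- stats::residuals(stats::lm(X[, i] ~ X[, rest]))
  rj <- stats::residuals(stats::lm(X[, j] ~ X[, rest]))
  stats::cor(ri, rj)
}
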