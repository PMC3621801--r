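#' Sample an Erdős–Rényi random graph
#'
#' Draws G(n, p): each of the n(n-1)/2 dyads is an independent
#' Bernoulli(p) edge.
#'
#' @param n graph order (number of nodes), at least 2.
#' @param p edge probability in \[0, 1\].
#' @param seed optional integer seed; when supplied, `set.seed(seed)` is
#'   called before sampling.
#' @return A binary `labeled_network` with labels `"v1".."vn"`.
#' @examples
#' g <- sample_er(25, 0.2, seed = 1)
#' network_size(g)
#' @export
sample_er <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be at least 2", call. = FALSE)
  if (!is.finite(p) || p < 0 || p > 1) {
    stop("'p' must be in [0, 1]", call. = FALSE)
  }
  W <- matrix(0, n, n)
  up <- upper.tri(W)
  W[up] <- stats::rbinom(sum(up), 1L, p)
  W <- W + t(W)
  labeled_network(W, labels = paste0("v", seq_len(n)))
}

# One random block: a correlation matrix with Markov (path) conditional
# dependence. Partial correlations on the path edges are drawn with
# magnitude in (pc_lo, pc_hi) and random signs; the standardized precision
# matrix is rejected unless positive definite, and the resulting
# correlation matrix is rejected unless every off-diagonal magnitude
# reaches min_abs. Near the upper magnitude bound the path sits close to
# the positive-definiteness boundary, which is what produces strong
# marginal correlations throughout the block.
.sample_block <- function(block_size, min_abs, pc_lo = 0.5, pc_hi = 0.65,
                          max_tries = 10000L) {
  m <- block_size
  if (m == 1L) return(matrix(1, 1, 1))
  for (try in seq_len(max_tries)) {
    pc <- sample(c(-1, 1), m - 1L, replace = TRUE) *
      stats::runif(m - 1L, pc_lo, pc_hi)
    K <- diag(m)
    for (i in seq_len(m - 1L)) K[i, i + 1L] <- K[i + 1L, i] <- -pc[i]
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-8) next
    R <- stats::cov2cor(solve(K))
    if (min(abs(R[upper.tri(R)])) >= min_abs) return(R)
  }
  stop(sprintf(paste0("block rejection sampling failed after %d tries ",
                      "(acceptance rate below %.2g); relax 'min_abs'"),
               max_tries, 1 / max_tries), call. = FALSE)
}

#' Sample a block-diagonal correlation population
#'
#' Builds a population correlation matrix consisting of independent
#' diagonal blocks, each a random correlation matrix whose off-diagonal
#' entries all have magnitude at least `min_abs` (enforced by rejection
#' sampling) and whose conditional-dependence structure is a path, so the
#' implied Gaussian graphical model of each block is a connected chain.
#' Entries outside the blocks are exactly zero.
#'
#' @param n_blocks number of diagonal blocks (default 6).
#' @param block_size nodes per block (default 5).
#' @param min_abs minimum absolute value of within-block off-diagonal
#'   entries, in (0, 1) (default 0.2).
#' @param seed optional integer seed.
#' @param max_tries rejection-sampling cap per block.
#' @return An object of class `"correlation_population"`: a list with
#'   `Omega` (the population correlation matrix, unit diagonal, positive
#'   definite), `n_blocks`, `block_size`, `min_abs`, and `block_index`
#'   (integer vector mapping variables to blocks). Variables are labelled
#'   `"v1".."vN"`.
#' @examples
#' pop <- sample_block_correlation(seed = 1)
#' dim(pop$Omega)
#' min(eigen(pop$Omega, only.values = TRUE)$values) > 0
#' @export
sample_block_correlation <- function(n_blocks = 6L, block_size = 5L,
                                     min_abs = 0.2, seed = NULL,
                                     max_tries = 10000L) {
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- as.integer(n_blocks)
  block_size <- as.integer(block_size)
  if (n_blocks < 1L || block_size < 1L || n_blocks * block_size < 2L) {
    stop("population must have at least 2 variables", call. = FALSE)
  }
  if (!is.finite(min_abs) || min_abs <= 0 || min_abs >= 1) {
    stop("'min_abs' must be in (0, 1)", call. = FALSE)
  }
  d <- n_blocks * block_size
  Omega <- matrix(0, d, d)
  block_index <- rep(seq_len(n_blocks), each = block_size)
  for (b in seq_len(n_blocks)) {
    idx <- which(block_index == b)
    Omega[idx, idx] <- .sample_block(block_size, min_abs,
                                     max_tries = max_tries)
  }
  labs <- paste0("v", seq_len(d))
  dimnames(Omega) <- list(labs, labs)
  structure(list(Omega = Omega, n_blocks = n_blocks,
                 block_size = block_size, min_abs = min_abs,
                 block_index = block_index),
            class = "correlation_population")
}

#' @export
print.correlation_population <- function(x, ...) {
  cat(sprintf(paste0("Block-diagonal correlation population: %d blocks ",
                     "of %d (dimension %d), min |entry| = %g\n"),
              x$n_blocks, x$block_size, x$n_blocks * x$block_size,
              x$min_abs))
  invisible(x)
}

#' Redraw a subset of blocks of a correlation population
#'
#' Used to simulate the alternative hypothesis of network inequality: a
#' fraction of the diagonal blocks (at least one) is independently redrawn
#' from the block sampler; all other entries are unchanged.
#'
#' @param population a [sample_block_correlation()] result.
#' @param min_fraction minimum fraction of blocks to redraw, in (0, 1\];
#'   the number redrawn is `max(1, ceiling(min_fraction * n_blocks))`.
#' @param seed optional integer seed.
#' @return A `correlation_population` with the selected blocks replaced.
#' @export
perturb_blocks <- function(population, min_fraction = 0.1, seed = NULL) {
  stopifnot(inherits(population, "correlation_population"))
  if (!is.finite(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    stop("'min_fraction' must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  k <- max(1L, as.integer(ceiling(min_fraction * population$n_blocks)))
  sel <- sample(population$n_blocks, k)
  out <- population
  for (b in sel) {
    idx <- which(population$block_index == b)
    out$Omega[idx, idx] <- .sample_block(population$block_size,
                                         population$min_abs)
  }
  out
}

#' Sample multivariate normal data
#'
#' Rows are i.i.d. N(0, Omega) draws.
#'
#' @param Omega a positive-definite covariance/correlation matrix, or a
#'   `correlation_population`.
#' @param n_samples number of rows.
#' @param seed optional integer seed.
#' @return A numeric matrix (`n_samples` x `ncol(Omega)`) with the
#'   population's variable labels as column names.
#' @export
sample_mvn <- function(Omega, n_samples, seed = NULL) {
  if (inherits(Omega, "correlation_population")) Omega <- Omega$Omega
  if (!is.null(seed)) set.seed(seed)
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stop("'n_samples' must be positive", call. = FALSE)
  X <- MASS::mvrnorm(n_samples, mu = rep(0, ncol(Omega)), Sigma = Omega)
  X <- matrix(X, nrow = n_samples)  # mvrnorm drops dims when n = 1
  colnames(X) <- colnames(Omega)
  X
}

.check_data_matrix <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("data matrix must be numeric", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- which(sds == 0 | !is.finite(sds))
    nm <- colnames(X)[bad]
    if (is.null(nm)) nm <- bad
    stop("zero-variance column(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  X
}

#' Thresholded Pearson correlation network
#'
#' Estimates all pairwise Pearson correlations and keeps r_ij as the edge
#' weight when |r_ij| >= rho, otherwise no edge.
#'
#' @param X samples-by-variables numeric matrix (>= 3 rows).
#' @param rho threshold in \[0, 1\].
#' @return A `labeled_network` with the column names of `X` as labels.
#' @export
correlation_network <- function(X, rho = 0.2) {
  X <- .check_data_matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 rows", call. = FALSE)
  if (ncol(X) < 2L) stop("need at least 2 columns", call. = FALSE)
  if (!is.finite(rho) || rho < 0 || rho > 1) {
    stop("'rho' must be in [0, 1]", call. = FALSE)
  }
  R <- stats::cor(X)
  R[abs(R) < rho] <- 0
  diag(R) <- 0
  labeled_network(R, labels = colnames(X))
}

#' Shrinkage estimate of a correlation matrix
#'
#' Linear shrinkage of the empirical Pearson correlation matrix toward the
#' identity: R* = (1 - lambda) R. When `lambda` is not supplied, the
#' analytic intensity lambda* = sum Var(r_ij) / sum r_ij^2 (clipped to
#' \[0, 1\]) is used, with Var(r_ij) estimated from the per-sample products
#' of the standardized data.
#'
#' @param X samples-by-variables numeric matrix (>= 3 rows).
#' @param lambda optional shrinkage intensity in \[0, 1\]; estimated when
#'   `NULL`.
#' @return A list with `R` (shrunken correlation matrix, unit diagonal)
#'   and `lambda`.
#' @export
shrinkage_correlation <- function(X, lambda = NULL) {
  X <- .check_data_matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 rows", call. = FALSE)
  Xs <- scale(X)
  R <- crossprod(Xs) / (n - 1)
  if (is.null(lambda)) {
    S1 <- crossprod(Xs)        # sum_k w_kij,  w_kij = x_ki x_kj
    S2 <- crossprod(Xs^2)      # sum_k w_kij^2
    var_r <- n / ((n - 1)^3) * (S2 - S1^2 / n)
    up <- upper.tri(R)
    den <- sum(R[up]^2)
    lambda <- if (den == 0) 1 else min(1, max(0, sum(var_r[up]) / den))
  } else {
    if (!is.finite(lambda) || lambda < 0 || lambda > 1) {
      stop("'lambda' must be in [0, 1]", call. = FALSE)
    }
  }
  Rs <- (1 - lambda) * R
  diag(Rs) <- 1
  dimnames(Rs) <- list(colnames(X), colnames(X))
  list(R = Rs, lambda = lambda)
}

#' Partial correlation matrix
#'
#' Computes pi_ij = -omega_ij / sqrt(omega_ii * omega_jj) from the inverse
#' (omega_ij) of a correlation matrix. The diagonal is set to 1 by
#' convention. Under multivariate normality, pi_ij = 0 exactly when
#' variables i and j are conditionally independent given the rest.
#'
#' @param R an invertible correlation matrix.
#' @param pseudo_inverse fall back to the Moore–Penrose pseudo-inverse
#'   when `R` is singular; the result then carries attribute
#'   `pseudo_inverse = TRUE`.
#' @return A symmetric matrix of partial correlations.
#' @export
partial_correlation <- function(R, pseudo_inverse = FALSE) {
  R <- as.matrix(R)
  om <- tryCatch(solve(R), error = function(e) {
    if (!pseudo_inverse) {
      stop("correlation matrix is singular; set pseudo_inverse = TRUE ",
           "to use the Moore-Penrose inverse", call. = FALSE)
    }
    structure(MASS::ginv(R), pseudo = TRUE)
  })
  used_pseudo <- isTRUE(attr(om, "pseudo"))
  P <- -om / sqrt(diag(om) %o% diag(om))
  P <- (P + t(P)) / 2
  diag(P) <- 1
  dimnames(P) <- dimnames(R)
  if (used_pseudo) attr(P, "pseudo_inverse") <- TRUE
  P
}

#' Gaussian graphical model configuration
#'
#' @param cutoff magnitude threshold on the shrunken partial correlation
#'   above which an edge is kept, in (0, 1\].
#' @param lambda optional fixed shrinkage intensity (estimated when
#'   `NULL`).
#' @return An object of class `"ggm_config"`.
#' @export
ggm_config <- function(cutoff = 0.5, lambda = NULL) {
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff > 1) {
    stop("'cutoff' must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(lambda) && (!is.finite(lambda) || lambda < 0 || lambda > 1)) {
    stop("'lambda' must be in [0, 1]", call. = FALSE)
  }
  structure(list(cutoff = cutoff, lambda = lambda), class = "ggm_config")
}

#' Shrinkage partial-correlation (GGM) network
#'
#' Estimates the shrunken correlation matrix, converts it to partial
#' correlations, and keeps pi_ij as the edge weight when |pi_ij| >=
#' `cutoff`. Estimation failures (non-finite partial correlations) raise a
#' catchable error of class `"netdiss_estimation_error"` so that
#' simulation callers can redraw.
#'
#' @param X samples-by-variables numeric matrix.
#' @param config a [ggm_config()] (cutoff 0.5 by default).
#' @return A `labeled_network` of thresholded partial correlations.
#' @export
ggm_network <- function(X, config = ggm_config()) {
  stopifnot(inherits(config, "ggm_config"))
  sc <- shrinkage_correlation(X, lambda = config$lambda)
  P <- tryCatch(partial_correlation(sc$R),
                error = function(e) .estimation_error(conditionMessage(e)))
  if (any(!is.finite(P))) {
    .estimation_error("non-finite partial correlation estimates")
  }
  P[abs(P) < config$cutoff] <- 0
  diag(P) <- 0
  labeled_network(P, labels = colnames(X))
}

.estimation_error <- function(msg) {
  stop(structure(class = c("netdiss_estimation_error", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}
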