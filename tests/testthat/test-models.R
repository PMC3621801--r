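test_that("Erdos-Renyi sampler obeys edge-probability extremes", {
  g0 <- sample_er(10, 0, seed = 1)
  expect_equal(network_size(g0), 0L)
  g1 <- sample_er(10, 1, seed = 1)
  expect_equal(network_size(g1), choose(10, 2))
  expect_error(sample_er(10, 1.2), "0, 1")
  expect_error(sample_er(1, 0.5), "at least 2")
})

test_that("Erdos-Renyi mean edge count matches binomial moments", {
  set.seed(2)
  counts <- replicate(10000, network_size(sample_er(25, 0.20)))
  se <- sqrt(300 * 0.2 * 0.8 / 10000)
  expect_lt(abs(mean(counts) - 60), 3 * se)
})

test_that("block correlation population has the stated structure", {
  pop <- sample_block_correlation(6, 5, 0.2, seed = 3)
  Om <- pop$Omega
  expect_equal(dim(Om), c(30L, 30L))
  expect_equal(diag(Om), setNames(rep(1, 30), colnames(Om)))
  expect_equal(Om, t(Om))
  off <- Om - diag(30)
  expect_equal(sum(off != 0), 6 * 5 * 4)  # exactly the within-block cells
  within <- outer(pop$block_index, pop$block_index, "==") & !diag(30)
  expect_true(all(abs(Om[within]) >= 0.2))
  expect_true(all(Om[!within & !diag(30)] == 0))
  expect_gt(min(eigen(Om, only.values = TRUE)$values), 0)
})

test_that("degenerate and repeated block populations stay valid", {
  expect_equal(sample_block_correlation(3, 1, 0.5, seed = 1)$Omega,
               diag(3), ignore_attr = TRUE)
  set.seed(4)
  for (rep in 1:100) {
    pop <- sample_block_correlation(2, 4, 0.2)
    expect_gt(min(eigen(pop$Omega, only.values = TRUE)$values), 0)
  }
})

test_that("perturb_blocks redraws the right number of blocks in place", {
  pop <- sample_block_correlation(6, 5, 0.2, seed = 5)
  out <- perturb_blocks(pop, 0.1, seed = 6)
  changed <- vapply(1:6, function(b) {
    idx <- which(pop$block_index == b)
    !identical(out$Omega[idx, idx], pop$Omega[idx, idx])
  }, logical(1))
  expect_equal(sum(changed), 1L)   # ceiling(0.1 * 6) with a minimum of 1
  # untouched blocks are bit-for-bit identical
  for (b in which(!changed)) {
    idx <- which(pop$block_index == b)
    expect_identical(out$Omega[idx, idx], pop$Omega[idx, idx])
  }
  # off-block zeros preserved
  expect_true(all(out$Omega[outer(pop$block_index, pop$block_index,
                                  "!=")] == 0))
  all_new <- perturb_blocks(pop, 1, seed = 7)
  changed_all <- vapply(1:6, function(b) {
    idx <- which(pop$block_index == b)
    !identical(all_new$Omega[idx, idx], pop$Omega[idx, idx])
  }, logical(1))
  expect_true(all(changed_all))
  expect_error(perturb_blocks(pop, 0), "0, 1")
})

test_that("multivariate normal sampler has the requested moments", {
  X <- sample_mvn(diag(4), 1e5, seed = 8)
  R <- cor(X)
  expect_lt(max(abs(R[upper.tri(R)])), 3 / sqrt(1e5))
  one <- sample_mvn(diag(3), 1, seed = 9)
  expect_equal(dim(one), c(1L, 3L))
  expect_true(all(is.finite(one)))
  pop <- sample_block_correlation(6, 5, 0.2, seed = 10)
  X200 <- sample_mvn(pop, 200)
  expect_equal(dim(X200), c(200L, 30L))
  expect_equal(colnames(X200), colnames(pop$Omega))
})

test_that("correlation network thresholds Pearson correlations", {
  set.seed(11)
  X <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("v", 1:4)))
  full <- correlation_network(X, 0)
  R <- cor(X); diag(R) <- 0
  expect_equal(full$W, R, ignore_attr = TRUE)
  expect_error(correlation_network(X, 1.01), "0, 1")
  # duplicated columns keep |r| = 1 at the maximal threshold
  Xd <- cbind(X, v5 = X[, 1])
  dup <- correlation_network(Xd, 1)
  expect_equal(network_size(dup), 1L)
  expect_equal(dup$W["v1", "v5"], 1)
  Xz <- X; Xz[, 2] <- 5
  expect_error(correlation_network(Xz, 0.2), "v2")
})

test_that("between-block edges are rare at n = 200, rho = 0.2", {
  pop <- sample_block_correlation(6, 5, 0.2, seed = 12)
  X <- sample_mvn(pop, 200, seed = 13)
  net <- correlation_network(X, 0.2)
  between <- outer(pop$block_index, pop$block_index, "!=")
  false_rate <- mean(net$W[between & upper.tri(net$W)] != 0)
  # null |r| > 0.2 at n = 200 has two-sided tail probability ~0.004
  expect_lt(false_rate, 0.03)
})

test_that("shrinkage intensity behaves at its limits", {
  set.seed(14)
  X <- matrix(rnorm(2000 * 6), 2000, 6)
  sc <- shrinkage_correlation(X)
  expect_gte(sc$lambda, 0); expect_lte(sc$lambda, 1)
  expect_gt(sc$lambda, 0.8)  # independent columns shrink hard
  raw <- shrinkage_correlation(X, lambda = 0)
  expect_equal(raw$R, cor(X), ignore_attr = TRUE, tolerance = 1e-12)
  idn <- shrinkage_correlation(X, lambda = 1)
  expect_equal(idn$R, diag(6), ignore_attr = TRUE)
  expect_error(shrinkage_correlation(X, lambda = 2), "0, 1")
})

test_that("partial correlation matches closed forms and zeros of R^-1", {
  expect_equal(partial_correlation(diag(4)), diag(4), ignore_attr = TRUE)
  # 3-variable equicorrelation: pi = r / (1 + r)
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  P <- partial_correlation(R)
  expect_equal(P[upper.tri(P)], rep(0.5 / 1.5, 3), tolerance = 1e-12)
  # off-diagonal zeros of the inverse are zeros of Pi
  B <- diag(4); B[1, 2] <- B[2, 1] <- 0.6; B[3, 4] <- B[4, 3] <- 0.4
  P2 <- partial_correlation(cov2cor(solve(B)))
  expect_equal(abs(P2[1, 3]) + abs(P2[1, 4]) + abs(P2[2, 3]) +
                 abs(P2[2, 4]), 0, tolerance = 1e-10)
})

test_that("partial correlation agrees with the regression-residual oracle", {
  set.seed(15)
  for (rep in 1:5) {
    pop <- sample_block_correlation(1, 4, 0.2)
    X <- sample_mvn(pop, 80)
    P <- partial_correlation(cor(X))
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(P[i, j], residual_pcor(X, i, j), tolerance = 1e-8)
    }
  }
})

test_that("singular correlation matrices need the pseudo-inverse flag", {
  R <- matrix(1, 3, 3)  # rank 1
  expect_error(partial_correlation(R), "singular|pseudo")
  P <- partial_correlation(R, pseudo_inverse = TRUE)
  expect_true(isTRUE(attr(P, "pseudo_inverse")))
  expect_true(all(is.finite(P)))
})

test_that("GGM network keeps within-block structure and rejects bad cutoffs", {
  expect_error(ggm_config(cutoff = 1.5), "0, 1")
  set.seed(16)
  # independent columns at large n: no partial correlation survives 0.5
  Xi <- matrix(rnorm(500 * 8), 500, 8,
               dimnames = list(NULL, paste0("v", 1:8)))
  expect_equal(network_size(ggm_network(Xi)), 0L)
  # block data: edges concentrate within blocks
  pop <- sample_block_correlation(6, 5, 0.2, seed = 17)
  X <- sample_mvn(pop, 200, seed = 18)
  net <- ggm_network(X)
  expect_gt(network_size(net), 0L)
  between <- outer(pop$block_index, pop$block_index, "!=")
  expect_equal(sum(net$W[between & upper.tri(net$W)] != 0), 0L)
  # cutoff above the largest |pi| empties the network
  high <- ggm_network(X, ggm_config(cutoff = 1))
  expect_lte(network_size(high), network_size(net))
})

test_that("estimators are deterministic in their inputs", {
  pop <- sample_block_correlation(6, 5, 0.2, seed = 19)
  X <- sample_mvn(pop, 120, seed = 20)
  expect_identical(ggm_network(X)$W, ggm_network(X)$W)
  expect_identical(correlation_network(X, 0.2)$W,
                   correlation_network(X, 0.2)$W)
})
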