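test_that("config rejects invalid settings", {
  expect_error(dissim_config(edge = FALSE, weight = FALSE), "at least one")
  expect_error(dissim_config(c = -1), "nonnegative")
  expect_error(dissim_config(zero_tol = -0.1), "nonnegative")
  expect_error(dissim_config(radius = 3), "radius")
  # radius 1 means no neighbour term
  expect_equal(dissim_config(neighbour = "constant", c = 1,
                             radius = 1)$neighbour, "none")
})

test_that("hand-evaluated node terms on the three-node toy", {
  p <- toy_pair()
  cfg <- dissim_config()
  # node 2 sees the discordant dyad 2-3 in both components
  expect_equal(node_dissim(p$O, p$T, 2, cfg), 2)
  expect_equal(node_dissim(p$O, p$T, 1, cfg), 0)
  expect_equal(node_dissim(p$O, p$O, 2, cfg), 0)
  expect_error(node_dissim(p$O, p$T, 9, cfg), "out of range")

  # weighted pair: only the weight component differs
  O <- matrix(0, 2, 2); O[1, 2] <- O[2, 1] <- 0.5
  T_ <- matrix(0, 2, 2); T_[1, 2] <- T_[2, 1] <- 0.8
  expect_equal(node_dissim(O, T_, 1, cfg), 0.3)
})

test_that("hand-evaluated neighbour terms on the three-node toy", {
  p <- toy_pair()
  expect_equal(neighbour_dissim(p$O, p$T, 1, dissim_config()), 0)
  cfg_c <- dissim_config(neighbour = "constant", c = 0.5)
  # Gamma(1) = {2}; d_12* excludes nodes 1 and 2, leaving the 2-3 dyad
  expect_equal(neighbour_dissim(p$O, p$T, 1, cfg_c), 1)
  cfg_w <- dissim_config(neighbour = "weighted")
  expect_equal(neighbour_dissim(p$O, p$T, 1, cfg_w), 2)
})

test_that("hand-evaluated D on the three-node toy", {
  p <- toy_pair()
  expect_equal(net_dissim(p$O, p$T), 4)
  expect_equal(net_dissim(p$O, p$T,
                          dissim_config(neighbour = "constant", c = 0.5)), 5)
  expect_equal(net_dissim(p$O, p$T,
                          dissim_config(neighbour = "weighted")), 6)
})

test_that("D is zero between a network and itself for every config", {
  set.seed(7)
  cfgs <- list(dissim_config(),
               dissim_config(edge = FALSE),
               dissim_config(weight = FALSE),
               dissim_config(neighbour = "constant", c = 2),
               dissim_config(neighbour = "weighted"),
               dissim_config(neighbour = "weighted_abs"))
  for (rep in 1:5) {
    net <- random_weighted(6)
    for (cfg in cfgs) expect_equal(net_dissim(net, net, cfg), 0)
  }
})

test_that("vectorized D matches the literal triple-loop definition", {
  set.seed(42)
  modes <- c("none", "constant", "weighted", "weighted_abs")
  for (rep in 1:8) {
    a <- random_weighted(7)
    b <- random_weighted(7)
    for (mode in modes) {
      cfg <- dissim_config(neighbour = mode, c = 0.7)
      expect_equal(net_dissim(a, b, cfg),
                   naive_dissim(a$W, b$W, neighbour = mode, cc = 0.7),
                   tolerance = 1e-12)
    }
    # component switches
    cfg_e <- dissim_config(edge = TRUE, weight = FALSE)
    expect_equal(net_dissim(a, b, cfg_e),
                 naive_dissim(a$W, b$W, weight = FALSE), tolerance = 1e-12)
    cfg_w <- dissim_config(edge = FALSE, weight = TRUE)
    expect_equal(net_dissim(a, b, cfg_w),
                 naive_dissim(a$W, b$W, edge = FALSE), tolerance = 1e-12)
  }
})

test_that("binary D without neighbours is 4 x symmetric-difference size", {
  # exhaustive over all unordered graph pairs for n = 3 and n = 4
  for (n in 3:4) {
    m <- n * (n - 1) / 2
    graphs <- lapply(seq_len(2^m) - 1L, function(code) {
      bits <- as.integer(intToBits(code))[seq_len(m)]
      W <- matrix(0, n, n)
      W[upper.tri(W)] <- bits
      W + t(W)
    })
    take <- if (n == 3) seq_along(graphs) else seq(1, length(graphs), 3)
    for (i in take) for (j in take) {
      expect_equal(net_dissim(labeled_network(graphs[[i]]),
                              labeled_network(graphs[[j]])),
                   4 * sym_diff_edges(graphs[[i]], graphs[[j]]))
    }
  }
  # random spot checks at n = 5
  set.seed(9)
  for (rep in 1:50) {
    a <- random_binary(5)
    b <- random_binary(5)
    expect_equal(net_dissim(a, b), 4 * sym_diff_edges(a$W, b$W))
  }
})

test_that("flipping a concordant dyad never decreases D (constant c)", {
  set.seed(13)
  cfg <- dissim_config(neighbour = "constant", c = 0.8)
  for (rep in 1:40) {
    a <- random_binary(6)
    b <- random_binary(6)
    d0 <- net_dissim(a, b, cfg)
    conc <- which(upper.tri(a$W) & (a$W == b$W), arr.ind = TRUE)
    if (nrow(conc) == 0) next
    ij <- conc[sample(nrow(conc), 1), ]
    W2 <- a$W
    W2[ij[1], ij[2]] <- W2[ij[2], ij[1]] <- 1 - W2[ij[1], ij[2]]
    d1 <- net_dissim(labeled_network(W2, a$labels), b, cfg)
    expect_gte(d1, d0)
  }
})

test_that("zero tolerance controls the edge indicator deterministically", {
  O <- matrix(0, 2, 2); O[1, 2] <- O[2, 1] <- 1e-9
  T_ <- matrix(0, 2, 2)
  cfg_strict <- dissim_config(weight = FALSE, zero_tol = 0)
  cfg_loose <- dissim_config(weight = FALSE, zero_tol = 1e-6)
  expect_equal(net_dissim(O, T_, cfg_strict), 2)  # both endpoints
  expect_equal(net_dissim(O, T_, cfg_loose), 0)
})

test_that("node decomposition sums to D and matches hand values", {
  p <- toy_pair()
  dec <- node_decomposition(p$O, p$T)
  expect_equal(unname(dec$contributions), c(0, 2, 2))
  expect_equal(dec$total, 4)

  dec0 <- node_decomposition(p$O, p$O)
  expect_equal(unname(dec0$contributions), c(0, 0, 0))

  set.seed(23)
  cfgs <- list(dissim_config(),
               dissim_config(neighbour = "constant", c = 0.4),
               dissim_config(neighbour = "weighted"),
               dissim_config(edge = FALSE, neighbour = "weighted_abs"))
  for (rep in 1:10) {
    a <- random_weighted(8)
    b <- random_weighted(8)
    for (cfg in cfgs) {
      dec <- node_decomposition(a, b, cfg)
      expect_equal(sum(dec$contributions), net_dissim(a, b, cfg),
                   tolerance = 1e-9)
      expect_equal(dec$total, sum(dec$contributions), tolerance = 1e-9)
    }
  }
})
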