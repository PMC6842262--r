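test_that("occurrence scores count signature membership", {
  uni <- c("a", "b", "c", "d")
  sigs <- c(replicate(20, c("a", "b"), simplify = FALSE),
            list(c("b", "c")))
  s <- occurrence_scores(sigs, uni)
  expect_equal(unname(s), c(20, 21, 1, 0))
  # double-counting identity: sum of scores = sum of signature sizes
  expect_equal(sum(s), sum(lengths(sigs)))
  expect_equal(unname(occurrence_scores(list(), uni)), rep(0, 4))
})

test_that("the weighted Laplacian matches its definition", {
  net <- weighted_network(data.frame(from = "A", to = "B", weight = 1),
                          nodes = c("A", "B", "C"))
  # scale the weight to 2 via direct construction to check the formula shape
  H <- as.matrix(build_laplacian(net, c("A", "B", "C")))
  expect_equal(H, matrix(c(1, -1, 0, -1, 1, 0, 0, 0, 0), 3,
                         dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  # H 1 = 0 exactly, symmetric, non-negative diagonal on random graphs
  for (seed in 1:3) {
    nodes <- sprintf("n%02d", 1:12)
    H2 <- as.matrix(build_laplacian(make_net(nodes, seed = seed), nodes))
    expect_equal(max(abs(rowSums(H2))), 0, tolerance = 1e-12)
    expect_equal(H2, t(H2))
    expect_true(all(diag(H2) >= 0))
  }
  expect_error(build_laplacian(make_net(c("X", "Y")), c("A", "B")), "outside")
})

test_that("two-node kernel matches the closed form; beta 0 is the identity", {
  net <- weighted_network(data.frame(from = "A", to = "B", weight = 1))
  H <- build_laplacian(net, c("A", "B"))
  K <- diffusion_kernel(H, 0.3)$kernel
  a <- (1 + exp(-0.6)) / 2
  b <- (1 - exp(-0.6)) / 2
  expect_equal(unname(K), matrix(c(a, b, b, a), 2), tolerance = 1e-10)

  K0 <- diffusion_kernel(H, 0)$kernel
  expect_equal(unname(K0), diag(2), tolerance = 1e-12)
  expect_error(diffusion_kernel(H, -0.1), "beta")
})

test_that("kernel matches a dense matrix-exponential oracle on random graphs", {
  for (n in c(20, 60, 200)) {
    nodes <- sprintf("n%03d", seq_len(n))
    H <- as.matrix(build_laplacian(make_net(nodes, p = 3 / n, seed = n), nodes))
    K <- diffusion_kernel(H, 0.3)$kernel
    # Ward's Pade scaling-and-squaring, independent of the eigen path
    oracle <- as.matrix(Matrix::expm(Matrix::Matrix(-0.3 * H)))
    expect_lt(max(abs(K - oracle)), 1e-8)
    expect_lt(max(abs(colSums(K) - 1)), 1e-8)     # doubly stochastic
    expect_lt(max(abs(K - t(K))), 1e-10)          # symmetric
    expect_gt(min(K), -1e-10)                     # non-negative up to roundoff
  }
})

test_that("diffusion conserves mass and leaves isolated genes untouched", {
  nodes <- c(sprintf("n%02d", 1:8), "iso")
  net <- make_net(nodes[1:8], seed = 4)
  net$nodes <- nodes
  op <- diffusion_kernel(build_laplacian(net, nodes), 0.3)
  s <- setNames(c(runif(8, 0, 5), 7), nodes)
  sb <- diffuse(op, s)
  expect_equal(sum(sb), sum(s), tolerance = 1e-8)
  expect_equal(unname(sb["iso"]), 7, tolerance = 1e-10)
  expect_error(diffuse(op, rev(s)), "ordering")
})

test_that("diffusion scores converge to raw scores as beta -> 0", {
  nodes <- sprintf("n%02d", 1:15)
  net <- make_net(nodes, seed = 6)
  H <- build_laplacian(net, nodes)
  s <- setNames(runif(15, 0, 10), nodes)
  sb <- diffuse(diffusion_kernel(H, 1e-8), s)
  expect_lt(max(abs(sb - s)), 1e-6)
})

test_that("star-graph symmetry: leaves share one strictly positive score", {
  leaves <- sprintf("leaf%d", 1:6)
  net <- weighted_network(data.frame(from = "hub", to = leaves, weight = 0.8))
  nodes <- c("hub", leaves)
  op <- diffusion_kernel(build_laplacian(net, nodes), 0.3)
  s <- setNames(c(10, rep(0, 6)), nodes)
  sb <- diffuse(op, s)
  expect_true(all(sb[leaves] > 0))
  expect_lt(diff(range(sb[leaves])), 1e-10)
})

test_that("permutation scores match exhaustive enumeration", {
  # edgeless graph: kernel = identity, so scores permute as-is;
  # each value appears twice per position over the 6 permutations
  net <- weighted_network(data.frame(from = character(), to = character(),
                                     weight = numeric()),
                          nodes = c("a", "b", "c"))
  op <- diffusion_kernel(build_laplacian(net, c("a", "b", "c")), 0.3)
  s <- setNames(c(10, 5, 1), c("a", "b", "c"))
  expect_equal(unname(permutation_scores(op, s, exhaustive = TRUE)),
               c(2 / 6, 4 / 6, 1))

  # constant score vector: every permuted diffusion equals the observed
  s2 <- setNames(rep(3, 3), c("a", "b", "c"))
  expect_equal(unname(permutation_scores(op, s2, exhaustive = TRUE)),
               rep(1, 3))

  # Monte-Carlo converges to the exhaustive values on a 6-gene weighted graph
  nodes <- sprintf("n%d", 1:6)
  net6 <- make_net(nodes, seed = 8)
  op6 <- diffusion_kernel(build_laplacian(net6, nodes), 0.3)
  s6 <- setNames(c(9, 4, 2, 1, 0, 0), nodes)
  exact <- permutation_scores(op6, s6, exhaustive = TRUE)
  mc <- permutation_scores(op6, s6, n_perm = 10000, seed = 123)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_true(all(abs(mc - exact) <= 3 * se + 1e-12))
})

test_that("permutation scores are reproducible and validate inputs", {
  nodes <- sprintf("n%d", 1:5)
  op <- diffusion_kernel(build_laplacian(make_net(nodes, seed = 2), nodes), 0.3)
  s <- setNames(runif(5), nodes)
  expect_identical(permutation_scores(op, s, 50, seed = 7),
                   permutation_scores(op, s, 50, seed = 7))
  expect_error(permutation_scores(op, s, 0, seed = 7), "n_perm")
})

test_that("significant-gene calling filters, sorts and ranks as specified", {
  calls <- call_significant_genes(c("g1", "g2", "g3"),
                                  raw_scores = c(5, 9, 2),
                                  diffusion_scores = c(5, 9, 2),
                                  perm_scores = c(0.001, 0.2, 0.04))
  expect_equal(calls$gene, c("g1", "g3"))
  expect_equal(calls$rank, 1:2)

  none <- call_significant_genes("g1", 1, 1, 0.05)  # 0.05 is not < 0.05
  expect_equal(nrow(none), 0L)

  tied <- call_significant_genes(c("g1", "g2"), c(1, 1), c(4, 9), c(0.01, 0.01))
  expect_equal(tied$gene, c("g2", "g1"))            # higher diffusion first
})
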