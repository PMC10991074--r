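test_that("the graphical lasso collapses to the plain inverse at zero penalty", {
  set.seed(1)
  p <- 6
  A <- matrix(rnorm(p * p), p)
  S <- stats::cov2cor(crossprod(A) / p + diag(p))
  Theta <- mistkit:::.glasso(S, 0)$Theta
  expect_equal(max(abs(Theta - solve(S))), 0, tolerance = 1e-6)
  # KKT conditions at a positive penalty: |S - W| bounded by lambda off-diagonal
  Theta2 <- mistkit:::.glasso(S, 0.05)$Theta
  gap <- abs((S - solve(Theta2))[upper.tri(S)])
  expect_lt(max(gap), 0.05 + 1e-6)
})

test_that("EBICglasso networks recover sparsity patterns", {
  # identity correlation: empty network
  net0 <- estimate_network(smooth_corr(diag(8)), n = 500)
  expect_true(all(net0$partial_correlations == 0))
  # two-block correlation: edges only within blocks
  blk <- function(p, r) { m <- matrix(r, p, p); diag(m) <- 1; m }
  R <- rbind(cbind(blk(5, 0.6), matrix(0, 5, 5)),
             cbind(matrix(0, 5, 5), blk(5, 0.6)))
  net <- estimate_network(smooth_corr(R), n = 1000)
  P <- net$partial_correlations
  expect_equal(sum(abs(P[1:5, 6:10])), 0)
  expect_true(all(abs(P[1:5, 1:5][upper.tri(diag(5))]) > 0))
  expect_equal(P, t(P))
  expect_equal(unname(diag(P)), rep(0, 10))
  # invariance to item reordering (up to the same permutation)
  dimnames(R) <- list(paste0("v", 1:10), paste0("v", 1:10))
  perm <- c(7, 2, 9, 4, 1, 10, 3, 6, 5, 8)
  net_p <- estimate_network(smooth_corr(R[perm, perm]), n = 1000)
  expect_equal(net_p$partial_correlations,
               estimate_network(smooth_corr(R), n = 1000)$partial_correlations[perm, perm],
               tolerance = 1e-5)
})

test_that("walktrap communities recover planted graph structure", {
  # two disconnected 4-cliques
  cl <- matrix(0.4, 4, 4); diag(cl) <- 0
  W <- rbind(cbind(cl, matrix(0, 4, 4)), cbind(matrix(0, 4, 4), cl))
  part <- detect_communities(W)
  expect_identical(part$K, 2L)
  expect_length(unique(part$membership[1:4]), 1)
  expect_length(unique(part$membership[5:8]), 1)
  # planted 4-community weighted graph with weak between-links
  set.seed(6)
  fac <- rep(1:4, each = 5)
  W4 <- matrix(0.05, 20, 20)
  for (k in 1:4) W4[fac == k, fac == k] <- 0.4
  diag(W4) <- 0
  part4 <- detect_communities(W4)
  expect_identical(part4$K, 4L)
  expect_true(all(vapply(1:4, function(k)
    length(unique(part4$membership[fac == k])) == 1, logical(1))))
  # a single clique is one community; an empty graph has no structure
  expect_identical(detect_communities(cl)$K, 1L)
  expect_error(detect_communities(matrix(0, 4, 4)),
               class = "mistkit_no_structure")
})

test_that("network loadings split node strength by dimension", {
  # toy: A-B (w=.5) within dim 1, A-C (w=.1) with C alone in dim 2
  W <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  W["A", "B"] <- W["B", "A"] <- 0.5
  W["A", "C"] <- W["C", "A"] <- 0.1
  part <- structure(list(membership = c(A = 1L, B = 1L, C = 2L), K = 2L),
                    class = "mist_partition")
  raw <- network_loadings(W, part, standardize = FALSE)
  expect_equal(raw["A", "Dim1"], 0.5)
  expect_equal(raw["A", "Dim2"], 0.1)
  expect_equal(raw["B", "Dim1"], 0.5)
  # an isolated node loads 0 everywhere
  W2 <- rbind(cbind(W, D = 0), D = 0)
  part2 <- structure(list(membership = c(A = 1L, B = 1L, C = 2L, D = 2L), K = 2L),
                     class = "mist_partition")
  raw2 <- network_loadings(W2, part2, standardize = FALSE)
  expect_equal(unname(raw2["D", ]), c(0, 0))
  # permuting dimension labels permutes loading columns identically
  part_sw <- structure(list(membership = c(A = 2L, B = 2L, C = 1L), K = 2L),
                       class = "mist_partition")
  sw <- network_loadings(W, part_sw)
  orig <- network_loadings(W, part)
  expect_equal(unname(sw[, c("Dim2", "Dim1")]), unname(orig[, c("Dim1", "Dim2")]))
})

test_that("standardized loadings track the published factor-loading anchors", {
  set.seed(8)
  n <- 4000
  fac <- rep(1:2, each = 9)
  lamv <- rep(c(0.40, 0.55, 0.70), 6)
  Th <- matrix(rnorm(n * 2), n, 2)
  Th[, 2] <- 0.3 * Th[, 1] + sqrt(1 - 0.09) * Th[, 2]
  lat <- vapply(1:18, function(j)
    lamv[j] * Th[, fac[j]] + sqrt(1 - lamv[j]^2) * rnorm(n), numeric(n))
  X <- (lat > 0) + 0L
  colnames(X) <- paste0("it", 1:18)
  e <- ega(X, n_lambda = 40)
  own <- vapply(seq_len(18), function(i)
    e$network_loadings[i, paste0("Dim", e$partition$membership[i])], numeric(1))
  means <- tapply(own, lamv, mean)
  # low/moderate/high factor loadings map near .15/.25/.35 and stay ordered
  expect_true(all(diff(means) > 0))
  expect_lt(abs(means[["0.4"]] - 0.15), 0.08)
  expect_lt(abs(means[["0.55"]] - 0.25), 0.08)
  expect_lt(abs(means[["0.7"]] - 0.35), 0.08)
})

test_that("weighted topological overlap flags redundant items", {
  # hand-computed wTO on a toy 4-node network against a brute-force oracle
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.5
  W[1, 3] <- W[3, 1] <- 0.3
  W[2, 3] <- W[3, 2] <- 0.4
  W[3, 4] <- W[4, 3] <- 0.2
  net <- structure(list(partial_correlations = W), class = "mist_network")
  u <- uva_redundancy(net, threshold = 2)  # threshold high: just the matrix
  A <- abs(W)
  k <- rowSums(A)
  for (i in 1:3) for (j in (i + 1):4) {
    oracle <- (sum(A[i, ] * A[, j]) + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    expect_equal(u$wto[i, j], oracle, tolerance = 1e-9)
  }
  # a duplicated column is flagged as redundant; independent items are not
  set.seed(10)
  n <- 800
  z <- rnorm(n)
  base <- vapply(1:6, function(j) 0.7 * z + sqrt(0.51) * rnorm(n), numeric(n))
  dup <- base[, 1] + rnorm(n, sd = 0.3)
  X <- (cbind(base, dup) > 0) + 0L
  colnames(X) <- c(paste0("a", 1:6), "a1dup")
  eu <- ega(X, n_lambda = 40)
  u2 <- uva_redundancy(eu$network, eu$network_loadings)
  expect_true(any((u2$pairs$item_i == "a1" & u2$pairs$item_j == "a1dup") |
                  (u2$pairs$item_i == "a1dup" & u2$pairs$item_j == "a1")))
  set.seed(11)
  Xi <- matrix(rbinom(1500 * 6, 1, 0.5), 1500, 6)
  colnames(Xi) <- paste0("ind", 1:6)
  net_i <- estimate_network(tetrachoric_matrix(Xi), n = 1500)
  if (any(net_i$partial_correlations != 0)) {
    expect_equal(nrow(uva_redundancy(net_i)$pairs), 0)
  } else {
    expect_true(all(net_i$partial_correlations == 0))
  }
})

test_that("TEFI is label-invariant, minimal at the true partition, and entropy-exact", {
  blk <- function(p, r) { m <- matrix(r, p, p); diag(m) <- 1; m }
  R <- matrix(0.05, 16, 16)
  fac <- rep(1:4, each = 4)
  for (k in 1:4) R[fac == k, fac == k] <- 0.6
  diag(R) <- 1
  t_true <- tefi(smooth_corr(R), fac)
  # relabeling leaves the value unchanged
  relab <- c(3L, 1L, 4L, 2L)[fac]
  expect_equal(tefi(smooth_corr(R), relab), t_true)
  # merging pairs of true dimensions degrades fit
  merged <- c(1L, 1L, 2L, 2L)[fac]
  expect_lt(t_true, tefi(smooth_corr(R), merged))
  # entropy oracle on a fixed 4x4 matrix
  M <- matrix(c(1, .5, .2, .1,
                .5, 1, .3, .2,
                .2, .3, 1, .4,
                .1, .2, .4, 1), 4, 4)
  lam <- eigen(M / sum(diag(M)), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(mistkit:::.vn_entropy(M), -sum(lam * log(lam)), tolerance = 1e-9)
})

test_that("the EGA pipeline recovers planted dimensionality on binary data", {
  hits2 <- vapply(1:3, function(s) {
    sim <- sim_factor_binary(1000, sizes = c(8, 8), loadings = c(0.6, 0.75),
                             seed = 40 + s)
    ega(sim$X, n_lambda = 40)$partition$K == 2L
  }, logical(1))
  expect_true(all(hits2))
  sim4 <- sim_factor_binary(1000, sizes = c(5, 5, 3, 3), loadings = c(0.65, 0.8),
                            seed = 77)
  e4 <- ega(sim4$X, n_lambda = 40)
  expect_identical(e4$partition$K, 4L)
  # every item loads at least weakly on its own dimension
  own <- vapply(seq_len(16), function(i)
    e4$network_loadings[i, paste0("Dim", e4$partition$membership[i])], numeric(1))
  expect_true(all(own >= 0.15))
})

test_that("bootEGA measures stability and degrades for ambiguous items", {
  sim <- sim_factor_binary(800, sizes = c(6, 6), loadings = c(0.65, 0.8), seed = 50)
  # an item loading equally on both dimensions
  set.seed(51)
  amb <- 0.45 * sim$theta[, 1] + 0.45 * sim$theta[, 2] +
    sqrt(1 - 2 * 0.45^2) * rnorm(800)
  X <- cbind(sim$X, amb = (amb > 0) + 0L)
  be <- boot_ega(X, n_boot = 40, seed = 52, n_lambda = 30)
  expect_true(all(be$item_stability >= 0 & be$item_stability <= 1))
  expect_true(all(be$structural_consistency >= 0 & be$structural_consistency <= 1))
  clean <- setdiff(colnames(X), "amb")
  expect_lt(be$item_stability[["amb"]], min(be$item_stability[clean]))
  # a single replicate concentrates the dimension distribution on itself
  be1 <- boot_ega(sim$X, n_boot = 1, seed = 53, n_lambda = 30)
  expect_length(be1$n_dims, 1)
  expect_equal(be1$median_dims, be1$n_dims[1])
})
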