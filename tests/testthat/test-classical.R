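test_that("the bivariate normal CDF matches a direct-integration oracle", {
  # oracle: P(Z1 <= h, Z2 <= k) by one-dimensional quadrature in base R
  oracle <- function(h, k, rho) integrate(function(x)
    dnorm(x) * pnorm((k - rho * x) / sqrt(1 - rho^2)), -Inf, h,
    rel.tol = 1e-10)$value
  for (rho in c(-0.95, -0.5, 0.2, 0.8, 0.99)) {
    for (hk in list(c(-1.5, 0.3), c(0, 0), c(0.7, -0.5))) {
      expect_equal(mistkit:::.pbvn(hk[1], hk[2], rho),
                   oracle(hk[1], hk[2], rho), tolerance = 1e-7)
    }
  }
})

test_that("tetrachoric estimation recovers latent correlations", {
  set.seed(2)
  n <- 6000
  z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(n)
  rho_hat <- tetrachoric((z1 > 0) + 0, (z2 > 0.3) + 0)
  expect_lt(abs(rho_hat - 0.5), 0.06)
  # a column against itself (zero off-cells, continuity-corrected)
  x <- rbinom(4000, 1, 0.5)
  expect_gte(tetrachoric(x, x), 0.99)
  # antisymmetry under flipping one coding
  y <- rbinom(4000, 1, 0.4)
  expect_equal(tetrachoric(x, y), -tetrachoric(x, 1 - y), tolerance = 1e-3)
  expect_error(tetrachoric(rep(1, 50), rbinom(50, 1, 0.5)),
               class = "mistkit_degenerate_item")
})

test_that("independent items give a near-diagonal tetrachoric matrix", {
  set.seed(3)
  X <- matrix(rbinom(5000 * 6, 1, 0.5), 5000, 6)
  R <- tetrachoric_matrix(X)
  expect_equal(unname(diag(R$values)), rep(1, 6))
  expect_lt(max(abs(R$values[upper.tri(R$values)])), 0.05)
  expect_error(tetrachoric_matrix(cbind(X, const = 1)),
               class = "mistkit_degenerate_item")
})

test_that("parallel analysis retains planted factors and nothing under noise", {
  sim <- sim_factor_binary(400, sizes = c(6, 6), loadings = 0.7, seed = 15)
  pa <- parallel_analysis(sim$X, n_sim = 150, seed = 8)
  expect_identical(pa$n_retained, 2L)
  # eigenvalues of a correlation matrix sum to p
  expect_equal(sum(pa$observed_eigenvalues), ncol(sim$X), tolerance = 1e-6)
  # pure noise: the modal retention over seeds is 0
  retained <- vapply(1:5, function(s) {
    set.seed(900 + s)
    Xn <- matrix(rbinom(500 * 8, 1, 0.5), 500, 8)
    parallel_analysis(Xn, n_sim = 60, seed = s)$n_retained
  }, integer(1))
  expect_identical(as.integer(names(which.max(table(retained)))), 0L)
})

test_that("EFA recovers block structure; rotation leaves communalities alone", {
  blk <- function(p, r) { m <- matrix(r, p, p); diag(m) <- 1; m }
  R <- rbind(cbind(blk(5, 0.5), matrix(0, 5, 5)),
             cbind(matrix(0, 5, 5), blk(5, 0.5)))
  dimnames(R) <- list(paste0("v", 1:10), paste0("v", 1:10))
  sol <- efa(smooth_corr(R), k = 2, method = "paf", rotation = "varimax")
  assign_hat <- apply(abs(sol$loadings), 1, which.max)
  expect_length(unique(assign_hat[1:5]), 1)
  expect_length(unique(assign_hat[6:10]), 1)
  expect_false(assign_hat[1] == assign_hat[6])
  expect_true(all(apply(abs(sol$loadings), 1, max) > 0.5))
  expect_true(all(apply(abs(sol$loadings), 1, min) < 0.1))
  expect_lt(sol$rmsr, 0.05)

  none <- efa(smooth_corr(R), k = 2, method = "paf", rotation = "none")
  expect_equal(sol$communalities, none$communalities, tolerance = 1e-6)
  uls <- efa(smooth_corr(R), k = 2, method = "uls", rotation = "varimax")
  expect_lt(uls$rmsr, 0.05)
})

test_that("varimax agrees with a brute-force rotation-angle grid search", {
  L <- matrix(c(0.8, 0.7, 0.3, 0.2,
                0.2, 0.3, 0.7, 0.8), 4, 2)
  # oracle: maximize the raw varimax criterion over a fine angle grid
  vmax_crit <- function(M) sum(apply(M^2, 2, var))
  best <- NULL
  for (ang in seq(0, pi / 2, length.out = 20001)) {
    Rm <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2)
    cand <- L %*% Rm
    if (is.null(best) || vmax_crit(cand) > vmax_crit(best)) best <- cand
  }
  rot <- stats::varimax(L, normalize = FALSE)
  got <- unclass(rot$loadings)
  # align column order/sign before comparing
  align <- function(M, ref) {
    if (sum(abs(M[, 1] - ref[, 1])) > sum(abs(M[, 2:1][, 1] - ref[, 1]))) M <- M[, 2:1]
    for (j in 1:2) if (sum(M[, j] * ref[, j]) < 0) M[, j] <- -M[, j]
    M
  }
  expect_equal(unname(align(got, best)), unname(best), tolerance = 1e-3)
})

test_that("3PL-implied communalities follow the loading conversion", {
  h2 <- communalities_from_3pl(data.frame(id = "x", a = 1.702))
  expect_equal(unname(h2), 0.5)
  a_grid <- seq(0.2, 9, length.out = 30)
  h2s <- communalities_from_3pl(data.frame(id = paste0("i", 1:30), a = a_grid))
  expect_true(all(diff(h2s) > 0))          # monotone in a
  expect_lt(h2s[1], 0.02)                  # a -> 0 gives h2 -> 0
  expect_gt(communalities_from_3pl(data.frame(id = "y", a = 100)), 0.99)
  expect_error(communalities_from_3pl(data.frame(id = "z", b = 1)),
               class = "mistkit_missing_parameter")
})

test_that("alpha matches the covariance formula and pruning removes planted junk", {
  set.seed(21)
  # hand-built 3-item check of k/(k-1) (1 - sum var_i / var_total)
  Y <- cbind(rbinom(40, 1, 0.6), rbinom(40, 1, 0.5), rbinom(40, 1, 0.4))
  a_hand <- (3 / 2) * (1 - sum(apply(Y, 2, var)) / var(rowSums(Y)))
  expect_equal(cronbach_alpha(Y), a_hand)

  # three identical columns: alpha = 1 and nothing is removed
  Z <- matrix(rbinom(60, 1, 0.5), 60, 1)[, c(1, 1, 1)]
  colnames(Z) <- paste0("z", 1:3)
  pr <- alpha_if_deleted_prune(Z)
  expect_equal(pr$alpha, 1)
  expect_length(pr$removed, 0)

  # 10 coherent items plus one independent noise item: noise goes first
  sim <- sim_factor_binary(500, sizes = 10, loadings = 0.65, seed = 33)
  X <- cbind(sim$X, junk = rbinom(500, 1, 0.5))
  pr2 <- alpha_if_deleted_prune(X)
  expect_equal(pr2$removed[1], "junk")
  # pruning never removes an item whose deletion lowers alpha
  expect_true(all(pr2$trace$gain[seq_along(pr2$removed)] > 0.001))
  expect_lte(pr2$alpha, 1)
})

test_that("omega recovers the closed-form general saturation of a bifactor model", {
  set.seed(9)
  n <- 2500; p <- 12
  g_load <- rep(0.6, p); s_load <- rep(0.5, p)
  fac <- rep(1:2, each = 6)
  G <- rnorm(n); S1 <- rnorm(n); S2 <- rnorm(n)
  lat <- vapply(seq_len(p), function(j)
    g_load[j] * G + s_load[j] * (if (fac[j] == 1) S1 else S2) +
      sqrt(1 - g_load[j]^2 - s_load[j]^2) * rnorm(n), numeric(n))
  X <- (lat > 0) + 0L
  colnames(X) <- paste0("it", seq_len(p))
  rel <- reliability_report(X, fac, cor_method = "tetrachoric")
  Rimp <- tcrossprod(g_load) + outer(fac, fac, "==") * tcrossprod(s_load)
  diag(Rimp) <- 1
  omega_oracle <- sum(g_load)^2 / sum(Rimp)
  expect_lt(abs(rel$omega_g - omega_oracle), 0.05)
  expect_true(all(c(rel$omega_g, rel$omega_f) >= 0 & c(rel$omega_g, rel$omega_f) <= 1))
  expect_lte(rel$alpha, 1)
  expect_equal(sum(rel$variance_decomposition$share_of_explained), 1)
})

test_that("omega degenerates gracefully and test-retest is exact on identical data", {
  set.seed(14)
  n <- 2000; p <- 10
  G <- rnorm(n)
  lat <- vapply(seq_len(p), function(j) 0.7 * G + sqrt(0.51) * rnorm(n), numeric(n))
  X <- (lat > 0) + 0L
  colnames(X) <- paste0("it", seq_len(p))
  fac <- rep(1:2, each = 5)
  rel <- reliability_report(X, fac, cor_method = "tetrachoric")
  # no group variance: the general factor carries (nearly) everything
  expect_gt(rel$phi, 0.9)
  expect_gt(rel$omega_g, 0.85)
  rel2 <- reliability_report(X, fac, retest = X)
  expect_equal(rel2$test_retest, 1)
  bad <- X[1:100, ]
  expect_error(reliability_report(X, fac, retest = bad),
               class = "mistkit_alignment_error")
})
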