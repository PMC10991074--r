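test_that("3PL trace lines have the right shape, midpoint and asymptotes", {
  expect_equal(icc_3pl(0.3, a = 2, b = 0.3, c = 0.5), 0.75)   # P(b) midpoint
  expect_equal(icc_3pl(50, a = 2, b = 0), 1, tolerance = 1e-12)
  expect_equal(icc_3pl(-50, a = 2, b = 0), 0.5, tolerance = 1e-12)
  # the steepest published item at theta = 0 (a = 8.59, b = -0.60)
  expect_equal(icc_3pl(0, a = 8.59, b = -0.60), 0.9971, tolerance = 1e-4)
  # strictly increasing, bounded in (c, 1)
  th <- seq(-6, 6, length.out = 201)
  P <- icc_3pl(th, a = 2.5, b = -0.3)
  expect_true(all(diff(P) > 0))
  expect_true(all(P > 0.5 & P < 1))
})

test_that("item information peaks near b with I(b) = a^2/12 and vanishes at extremes", {
  expect_equal(item_information(0.4, a = 2, b = 0.4), 4 / 12)
  expect_equal(item_information(-1, a = 3.5, b = -1), 3.5^2 / 12)
  th <- seq(-6, 6, length.out = 121)
  I <- item_information(th, a = 2.4, b = 0.2)
  expect_true(all(I >= 0))
  expect_lt(item_information(30, a = 2, b = 0), 1e-8)
  expect_lt(item_information(-30, a = 2, b = 0), 1e-8)
})

test_that("test information is additive and peaks in the scale's working range", {
  one <- data.frame(a = 2, b = 0.1)
  th <- seq(-4, 4, length.out = 81)
  ti1 <- test_information(one, th)
  expect_equal(ti1$information, item_information(th, 2, 0.1))
  ti2 <- test_information(rbind(one, one), th)
  expect_equal(ti2$information, 2 * ti1$information)
  expect_error(test_information(data.frame(a = numeric(0), b = numeric(0))),
               class = "mistkit_empty_model")
  # packaged MIST-20 curve peaks between theta = -2 and 1
  bank <- builtin_bank("MIST-20")
  ti <- test_information(bank, seq(-4, 4, length.out = 401), split = TRUE)
  peak <- ti$theta[which.max(ti$information)]
  expect_gt(peak, -2)
  expect_lt(peak, 1)
  expect_equal(ti$information, ti$real + ti$fake)
})

test_that("EAP matches a dense-grid posterior-integration oracle", {
  pars <- data.frame(a = 1, b = 0, c = 0.5)
  # oracle: direct numerical integration on a 1e5-point grid
  grid <- seq(-8, 8, length.out = 1e5)
  w <- dnorm(grid)
  oracle <- function(pattern, params) {
    loglik <- rep(0, length(grid))
    for (j in seq_len(nrow(params))) {
      P <- icc_3pl(grid, params$a[j], params$b[j], params$c[j])
      loglik <- loglik + log(pmax(if (pattern[j] == 1) P else 1 - P, 1e-300))
    }
    loglik <- loglik - max(loglik)
    post <- exp(loglik) * w
    sum(grid * post) / sum(post)
  }
  expect_equal(estimate_theta_eap(pars, 1)$theta, oracle(1, pars),
               tolerance = 1e-3)
  pars8 <- builtin_bank("MIST-8")$items
  set.seed(5)
  for (i in 1:5) {
    pat <- rbinom(8, 1, 0.7)
    expect_equal(estimate_theta_eap(pars8, pat)$theta, oracle(pat, pars8),
                 tolerance = 1e-3)
  }
})

test_that("EAP is monotone in the response pattern", {
  pars <- builtin_bank("MIST-20")$items
  all_wrong <- estimate_theta_eap(pars, rep(0, 20))$theta
  all_right <- estimate_theta_eap(pars, rep(1, 20))$theta
  expect_gt(all_right, all_wrong)
  set.seed(12)
  ok <- vapply(1:50, function(i) {
    pat <- rbinom(20, 1, 0.6)
    j <- which(pat == 0)[1]
    if (is.na(j)) return(TRUE)
    flipped <- pat; flipped[j] <- 1
    estimate_theta_eap(pars, flipped)$theta >= estimate_theta_eap(pars, pat)$theta
  }, logical(1))
  expect_true(all(ok))
  expect_error(estimate_theta_eap(pars, rep(NA, 20)),
               class = "mistkit_empty_response")
  relaxed <- estimate_theta_eap(pars, rep(NA, 20), strict = FALSE)
  expect_equal(relaxed$theta, 0)
})

test_that("EM calibration is monotone in log-likelihood and recovers structure", {
  sim <- sim_3pl_binary(800, a = c(1.8, 2.2, 2.6, 3.0, 2.0),
                        b = c(-0.8, -0.4, 0, 0.4, 0.8), seed = 42)
  fit <- suppressWarnings(calibrate_3pl_em(sim$X))
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_equal(fit$params$c, rep(0.5, 5))
  # difficulty ordering is recovered
  expect_equal(order(fit$params$b), 1:5)
  expect_equal(unname(coef(fit)[, "b"]), fit$params$b)
  # consistency: at larger n the estimates tighten around the truth
  sim2 <- sim_3pl_binary(4000, a = c(1.8, 2.2, 2.6, 3.0, 2.0),
                         b = c(-0.8, -0.4, 0, 0.4, 0.8), seed = 43)
  fit2 <- calibrate_3pl_em(sim2$X)
  expect_lt(sqrt(mean((fit2$params$b - c(-0.8, -0.4, 0, 0.4, 0.8))^2)), 0.15)
})

test_that("calibration rejects degenerate items and warns on small samples", {
  sim <- sim_3pl_binary(300, a = c(2, 2, 2), b = c(-0.5, 0, 0.5), seed = 3)
  X <- cbind(sim$X, allright = 1L)
  expect_error(calibrate_3pl_em(X), class = "mistkit_degenerate_item")
  expect_error(calibrate_3pl_em(X), "allright")
  small <- sim_3pl_binary(120, a = c(2, 2, 2), b = c(-0.5, 0, 0.5), seed = 4)
  expect_warning(calibrate_3pl_em(small$X), class = "mistkit_small_n")
})

test_that("DIF likelihood-ratio screen is null on identical groups and finds planted DIF", {
  a <- c(2, 2.5, 2.2, 1.8, 2.6, 2.1)
  b <- c(-0.8, -0.4, -0.1, 0.1, 0.4, 0.8)
  sim <- sim_3pl_binary(600, a, b, seed = 20)
  # the same data duplicated into two "groups": no signal anywhere
  X2 <- rbind(sim$X, sim$X)
  grp <- rep(1:2, each = 600)
  dif <- suppressWarnings(dif_likelihood_ratio(X2, grp))
  expect_true(all(dif$chi2 < 1e-4))
  expect_false(any(dif$flagged))
  expect_error(dif_likelihood_ratio(sim$X, rep(1, 600)),
               class = "mistkit_group_error")

  # planted difficulty shift of +1.0 in group 2 on item 3
  hits <- vapply(1:5, function(seed) {
    set.seed(seed * 100)
    n <- 500
    th1 <- rnorm(n); th2 <- rnorm(n)
    b2 <- b; b2[3] <- b[3] + 1.0
    X1 <- vapply(1:6, function(j) rbinom(n, 1, icc_3pl(th1, a[j], b[j])), numeric(n))
    X2 <- vapply(1:6, function(j) rbinom(n, 1, icc_3pl(th2, a[j], b2[j])), numeric(n))
    X <- rbind(X1, X2); colnames(X) <- paste0("it", 1:6)
    dif <- dif_likelihood_ratio(X, rep(1:2, each = n))
    dif$flagged[3]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("DIF false-positive rate is near the nominal level", {
  a <- c(2, 2.5, 2.2, 1.8, 2.6, 2.1)
  b <- c(-0.8, -0.4, -0.1, 0.1, 0.4, 0.8)
  flags <- vapply(1:10, function(seed) {
    sim <- sim_3pl_binary(800, a, b, seed = 500 + seed)
    dif <- dif_likelihood_ratio(sim$X, rep(1:2, each = 400))
    mean(dif$flagged)
  }, numeric(1))
  # 60 item-tests at alpha = .05: the pooled flag rate stays near 5%
  expect_lt(mean(flags), 0.15)
})
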