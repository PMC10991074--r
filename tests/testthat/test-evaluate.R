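test_that("the paired test matches hand computation and degenerates cleanly", {
  # differences 0,1,2,3,4: mean 2, SD sqrt(2.5), t = 2/(sqrt(2.5)/sqrt(5))
  res <- paired_change_test(rep(0, 5), c(0, 1, 2, 3, 4))
  expect_equal(res$mean_diff, 2)
  expect_equal(res$t, 2.828, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.047, tolerance = 0.01)
  expect_equal(res$d_z, 2 / sqrt(2.5), tolerance = 1e-9)
  expect_true(res$ci_lower <= res$mean_diff && res$mean_diff <= res$ci_upper)
  # identical pre/post: a null result, not an error
  same <- paired_change_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(c(same$t, same$d_z), c(0, 0))
  expect_equal(same$p, 1)
  # constant nonzero shift has no variance to test against
  expect_error(paired_change_test(c(1, 2, 3), c(2, 3, 4)),
               class = "mistkit_degenerate_variance")
})

test_that("the paired test is antisymmetric and d_z * sqrt(n) equals t", {
  set.seed(28)
  pre <- rnorm(40); post <- pre + rnorm(40, 0.3)
  ab <- paired_change_test(pre, post)
  ba <- paired_change_test(post, pre)
  expect_equal(ab$mean_diff, -ba$mean_diff)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$d_z, -ba$d_z)
  expect_equal(ab$d_z * sqrt(40), ab$t, tolerance = 1e-9)
})

test_that("paired scoring runs across all five dimensions with id alignment", {
  bank <- builtin_bank("MIST-8")
  sim <- simulate_responses(bank, respondent_model(), sim_config(60, seed = 29))
  pre <- score_matrix(bank, sim$responses)
  post <- pre
  post$f <- pmin(post$f + 1L, 4L)
  res <- paired_change_test(pre, post)
  expect_setequal(res$dimension, c("V", "r", "f", "d", "n"))
  expect_gt(res$mean_diff[res$dimension == "f"], 0)
  shuffled <- post[sample(nrow(post)), ]
  res2 <- paired_change_test(pre, shuffled)
  expect_equal(res2$mean_diff, res$mean_diff)
  bad <- post; bad$respondent_id[1] <- "stranger"
  expect_error(paired_change_test(pre, bad), class = "mistkit_alignment_error")
})

test_that("power utilities reproduce printed sample sizes and round-trip", {
  expect_equal(required_n_ttest(d = 0.25, alpha = 0.05, power = 0.90)$n_int, 338L)
  expect_equal(required_n_ttest(d = 0.5, alpha = 0.05, power = 0.80)$n_int, 64L)
  expect_equal(required_n_correlation(r = 0.15)$n_int, 463L)
  expect_equal(required_n_correlation(r = 0.10)$n_real, 1046.7, tolerance = 1e-3)
  # round trip: power at n_int meets the target, at n_int - 1 it does not
  sol <- required_n_ttest(d = 0.25)
  pw <- function(n) power.t.test(n = n, delta = 0.25, sd = 1, sig.level = 0.05,
                                 type = "two.sample")$power
  expect_gte(pw(sol$n_int), 0.90)
  expect_lt(pw(sol$n_int - 1), 0.90)
  # monotonicity in the effect size
  ns <- vapply(c(0.2, 0.3, 0.5, 0.8), function(d) required_n_ttest(d)$n_real, 0)
  expect_true(all(diff(ns) < 0))
  nr <- vapply(c(0.1, 0.2, 0.4), function(r) required_n_correlation(r)$n_real, 0)
  expect_true(all(diff(nr) < 0))
  expect_error(required_n_ttest(d = 0.5, alpha = 0.5, power = 0.2),
               class = "mistkit_infeasible")
  expect_error(required_n_correlation(r = 1.2), class = "mistkit_effect_error")
})

test_that("incremental validity matches hand-computed R2 and ignores noise", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2.1, 4.2, 5.8, 8.3, 9.9, 12.2)  # ~ 2x + noise
  res <- incremental_validity(y, base = NULL, added = data.frame(x = x))
  ybar <- mean(y)
  fit <- lm(y ~ x)
  r2_hand <- 1 - sum(residuals(fit)^2) / sum((y - ybar)^2)
  expect_equal(res$r2_full, r2_hand, tolerance = 1e-9)
  # outcome equal to a predictor: perfect fit
  perfect <- suppressWarnings(  # lm warns about the (intended) perfect fit
    incremental_validity(x, base = NULL, added = data.frame(x = x)))
  expect_equal(perfect$r2_full, 1)
  # a pure-noise addition buys (at most) nothing in adjusted R2, on average
  set.seed(30)
  deltas <- vapply(1:25, function(i) {
    z <- rnorm(120); y2 <- z + rnorm(120)
    incremental_validity(y2, base = data.frame(z = z),
                         added = data.frame(noise = rnorm(120)))$delta_r2
  }, numeric(1))
  expect_lt(mean(deltas), 0.005)
  # collinearity is an error
  expect_error(incremental_validity(y, base = data.frame(x = x),
                                    added = data.frame(x2 = x)),
               class = "mistkit_collinearity")
})

test_that("a simulated fake-news intervention dissociates f from r", {
  bank <- builtin_bank("MIST-8")
  hits <- vapply(1:5, function(s) {
    n <- 300
    set.seed(600 + s)
    th <- data.frame(theta_r = rnorm(n), theta_f = rnorm(n))
    pre <- simulate_responses(bank, respondent_model(), sim_config(n, seed = 700 + s),
                              thetas = th)
    th_post <- th
    th_post$theta_f <- th_post$theta_f + 0.3
    post <- simulate_responses(bank, respondent_model(), sim_config(n, seed = 800 + s),
                               thetas = th_post)
    res <- paired_change_test(score_matrix(bank, pre$responses),
                              score_matrix(bank, post$responses))
    res$mean_diff[res$dimension == "f"] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # and the real-news change centers near zero across those runs
  set.seed(1000)
  n <- 400
  th <- data.frame(theta_r = rnorm(n), theta_f = rnorm(n))
  pre <- simulate_responses(bank, respondent_model(), sim_config(n, seed = 1001),
                            thetas = th)
  th$theta_f <- th$theta_f + 0.3
  post <- simulate_responses(bank, respondent_model(), sim_config(n, seed = 1002),
                             thetas = th)
  res <- paired_change_test(score_matrix(bank, pre$responses),
                            score_matrix(bank, post$responses))
  expect_lt(abs(res$mean_diff[res$dimension == "r"]), 0.25)
})
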