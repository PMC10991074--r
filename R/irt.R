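#' Three-parameter-logistic item response curves
#'
#' The 3PL model gives the probability of a correct binary judgment as
#' \deqn{P(\theta) = c + (1 - c) / (1 + e^{-a(\theta - b)})}
#' with discrimination `a`, difficulty `b` and guessing floor `c`. For a
#' two-alternative real/fake judgment the guessing floor is fixed at
#' `c = 0.5`, so `P` ranges over (0.5, 1) and `P(b) = 0.75`. The logistic
#' metric is used as-is, without the historical 1.702 normal-ogive scaling
#' constant, matching mainstream IRT software defaults.
#'
#' `item_information()` is the Fisher information of a single item,
#' \deqn{I(\theta) = a^2 (Q/P) ((P - c)/(1 - c))^2,} which at `theta = b`
#' with `c = 0.5` equals `a^2/12`. `test_information()` sums item
#' information over the bank, optionally split by real/fake subscale.
#'
#' @param theta latent trait value(s).
#' @param a discrimination (> 0).
#' @param b difficulty.
#' @param c guessing floor in \[0, 1).
#' @return Probabilities, resp. information values, vectorized over `theta`.
#' @examples
#' icc_3pl(0, a = 8.59, b = -0.60)  # the steepest MIST-20 item at theta = 0
#' item_information(0.5, a = 2, b = 0.5)  # a^2 / 12
#' @export
icc_3pl <- function(theta, a, b, c = 0.5) {
  c + (1 - c) / (1 + exp(-a * (theta - b)))
}

#' @rdname icc_3pl
#' @export
item_information <- function(theta, a, b, c = 0.5) {
  P <- icc_3pl(theta, a, b, c)
  a^2 * ((1 - P) / P) * ((P - c) / (1 - c))^2
}

#' @param params a data frame (or `mist_bank` items) with columns `a`, `b`
#'   and optionally `c` (defaults to 0.5) and `veracity`.
#' @param split if `TRUE` and `params` has a `veracity` column, also return
#'   per-subscale (real/fake) information curves.
#' @rdname icc_3pl
#' @export
test_information <- function(params, theta = seq(-6, 6, length.out = 121),
                             split = FALSE) {
  params <- .as_params(params)
  if (nrow(params) == 0) mist_stop("empty_model", "no items in the parameter set")
  info <- vapply(seq_len(nrow(params)), function(j)
    item_information(theta, params$a[j], params$b[j], params$c[j]),
    numeric(length(theta)))
  info <- matrix(info, nrow = length(theta))
  out <- data.frame(theta = theta, information = rowSums(info))
  if (split && "veracity" %in% names(params)) {
    for (v in unique(params$veracity)) {
      out[[v]] <- rowSums(info[, params$veracity == v, drop = FALSE])
    }
  }
  out
}

# stable log P and log(1 - P) for the 3PL: 1 - P = (1 - c) / (1 + e^{a(th-b)})
.icc_logp <- function(theta, a, b, c) {
  log(pmax(icc_3pl(theta, a, b, c), 1e-300))
}
.icc_logq <- function(theta, a, b, c) {
  log1p(-c) + stats::plogis(a * (theta - b), lower.tail = FALSE, log.p = TRUE)
}

.as_params <- function(params) {
  if (inherits(params, "mist_bank")) params <- params$items
  if (inherits(params, "mist_3pl")) params <- params$params
  params <- as.data.frame(params)
  if (!all(c("a", "b") %in% names(params))) {
    mist_stop("missing_parameter", "item parameters need columns 'a' and 'b'")
  }
  if (any(is.na(params$a)) || any(is.na(params$b))) {
    mist_stop("missing_parameter", "item parameters contain missing a/b values")
  }
  if (!"c" %in% names(params) || all(is.na(params$c))) {
    params$c <- rep(0.5, nrow(params))
  }
  params$c[is.na(params$c)] <- 0.5
  params
}

# fixed Gauss-type quadrature used throughout: equally spaced nodes with
# standard-normal prior mass, renormalized
.quad <- function(n_nodes = 61, range = c(-6, 6)) {
  nodes <- seq(range[1], range[2], length.out = n_nodes)
  w <- dnorm(nodes)
  list(nodes = nodes, weights = w / sum(w))
}

#' EAP ability estimation under the 3PL
#'
#' Expected-a-posteriori estimate of the latent trait for one response
#' pattern, under a standard-normal prior, using fixed quadrature (61
#' equally spaced nodes on \[-6, 6\] by default; at that resolution the
#' estimate agrees with a dense-grid numerical integration to better than
#' 1e-3).
#'
#' @param params item parameters (columns `a`, `b`, optional `c`).
#' @param pattern 0/1 responses aligned to the rows of `params`; `NA`
#'   entries are skipped.
#' @param n_nodes,range quadrature resolution.
#' @param strict if `TRUE` (default) an all-missing pattern is an error;
#'   otherwise the prior mean/SD (0, 1) is returned.
#' @return A list of class `mist_theta`: `theta` (posterior mean), `sd`
#'   (posterior SD), `method = "EAP"`, `n_answered`.
#' @export
estimate_theta_eap <- function(params, pattern, n_nodes = 61, range = c(-6, 6),
                               strict = TRUE) {
  params <- .as_params(params)
  stopifnot(length(pattern) == nrow(params))
  keep <- !is.na(pattern)
  if (!any(keep)) {
    if (strict) mist_stop("empty_response", "no answered items in the pattern")
    return(structure(list(theta = 0, sd = 1, method = "EAP", n_answered = 0L),
                     class = "mist_theta"))
  }
  q <- .quad(n_nodes, range)
  x <- as.numeric(pattern[keep])
  pj <- params[keep, , drop = FALSE]
  loglik <- numeric(length(q$nodes))
  for (j in seq_len(nrow(pj))) {
    loglik <- loglik + x[j] * .icc_logp(q$nodes, pj$a[j], pj$b[j], pj$c[j]) +
      (1 - x[j]) * .icc_logq(q$nodes, pj$a[j], pj$b[j], pj$c[j])
  }
  lw <- loglik + log(q$weights)
  lw <- lw - max(lw)
  post <- exp(lw) / sum(exp(lw))
  theta <- sum(q$nodes * post)
  sd_post <- sqrt(max(sum((q$nodes - theta)^2 * post), .Machine$double.eps))
  structure(list(theta = theta, sd = sd_post, method = "EAP",
                 n_answered = sum(keep)), class = "mist_theta")
}

#' @export
print.mist_theta <- function(x, ...) {
  cat(sprintf("<EAP theta> %.3f (posterior SD %.3f, %d items)\n",
              x$theta, x$sd, x$n_answered))
  invisible(x)
}

# marginal log-likelihood of binary data X (n x p) under params at quadrature q
.mml_loglik <- function(X, params, q) {
  logP <- vapply(seq_len(nrow(params)), function(j)
    .icc_logp(q$nodes, params$a[j], params$b[j], params$c[j]),
    numeric(length(q$nodes)))
  logQ <- vapply(seq_len(nrow(params)), function(j)
    .icc_logq(q$nodes, params$a[j], params$b[j], params$c[j]),
    numeric(length(q$nodes)))
  ll_ik <- X %*% t(logP) + (1 - X) %*% t(logQ)   # n x K
  lw <- sweep(ll_ik, 2, log(q$weights), `+`)
  m <- apply(lw, 1, max)
  sum(m + log(rowSums(exp(lw - m))))
}

#' Marginal maximum likelihood 3PL calibration (EM)
#'
#' Fits discrimination and difficulty per item by marginal maximum
#' likelihood over a fixed quadrature grid, with the guessing parameter held
#' fixed (at 0.5 by default, the chance level of a binary real/fake
#' judgment). The E step computes posterior weights of each respondent over
#' the quadrature nodes; the M step maximizes each item's expected
#' log-likelihood under box constraints `a` in (0.05, 10\], `b` in
#' \[-6, 6\]. Iteration stops when the largest parameter change falls below
#' `tol_param` or the marginal log-likelihood improves by less than
#' `tol_loglik`, up to `max_cycles` cycles.
#'
#' @param data 0/1 matrix or data frame, respondents in rows, items in
#'   columns (column names become item ids).
#' @param fixed_c the guessing floor, fixed for all items.
#' @param max_cycles,tol_param,tol_loglik EM controls.
#' @param n_nodes,range quadrature resolution.
#' @return An object of class `mist_3pl` with elements `params` (data frame
#'   `id`, `a`, `b`, `c`), `loglik_trace` (marginal log-likelihood per EM
#'   cycle, non-decreasing), `converged`, `n_cycles`, `n`, `call`. Methods:
#'   `print`, `summary`, `coef`, `logLik`, `plot`.
#' @examples
#' \donttest{
#' sim <- simulate_item_pool(pool_spec(n_factors = 1, items_per_factor = 5),
#'                           sim_config(n = 500, seed = 1))
#' fit <- calibrate_3pl_em(sim$data)
#' coef(fit)
#' }
#' @export
calibrate_3pl_em <- function(data, fixed_c = 0.5, max_cycles = 500,
                             tol_param = 1e-4, tol_loglik = 1e-6,
                             n_nodes = 61, range = c(-6, 6)) {
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("item_", seq_len(ncol(X)))
  if (any(is.na(X)) || !all(X %in% c(0, 1))) {
    mist_stop("parse_error", "calibration data must be complete 0/1")
  }
  n <- nrow(X); p <- ncol(X)
  pbar <- colMeans(X)
  const <- pbar %in% c(0, 1)
  if (any(const)) mist_stop("degenerate_item", paste0(
    "constant (all-correct or all-incorrect) item(s): ",
    paste(colnames(X)[const], collapse = ", ")))
  if (n < 200) mist_warn("small_n", paste0(
    "n = ", n, " respondents; 3PL calibration is recommended with n >= 200"))

  q <- .quad(n_nodes, range)
  K <- length(q$nodes)
  # starts: unit discrimination, difficulty from guessing-adjusted proportions
  pstar <- pmin(pmax((pbar - fixed_c) / (1 - fixed_c), 0.02), 0.98)
  a <- rep(1, p)
  b <- -qnorm(pstar)
  lower <- c(0.05, range[1]); upper <- c(10, range[2])

  item_obj <- function(par, rbar, nbar) {
    -sum(rbar * .icc_logp(q$nodes, par[1], par[2], fixed_c) +
         (nbar - rbar) * .icc_logq(q$nodes, par[1], par[2], fixed_c))
  }
  item_grad <- function(par, rbar, nbar) {
    # core = dl/dP * (1-c) S (1-S); the (nbar - rbar)/(1-P) term simplifies
    # to S exactly, which stays finite where 1-P underflows
    S <- stats::plogis(par[1] * (q$nodes - par[2]))
    P <- fixed_c + (1 - fixed_c) * S
    core <- rbar * (1 - fixed_c) * S * (1 - S) / pmax(P, 1e-300) -
      (nbar - rbar) * S
    -c(sum(core * (q$nodes - par[2])), -par[1] * sum(core))
  }

  trace <- numeric(0)
  converged <- FALSE
  cycle <- 0L
  ll_prev <- -Inf
  while (cycle < max_cycles) {
    cycle <- cycle + 1L
    # E step
    logP <- vapply(seq_len(p), function(j) .icc_logp(q$nodes, a[j], b[j], fixed_c), numeric(K))
    logQ <- vapply(seq_len(p), function(j) .icc_logq(q$nodes, a[j], b[j], fixed_c), numeric(K))
    lw <- X %*% t(logP) + (1 - X) %*% t(logQ)
    lw <- sweep(lw, 2, log(q$weights), `+`)
    m <- apply(lw, 1, max)
    ll <- sum(m + log(rowSums(exp(lw - m))))
    trace <- c(trace, ll)
    post <- exp(lw - m) / rowSums(exp(lw - m))   # n x K
    nbar <- colSums(post)
    rbar <- crossprod(X, post)                   # p x K
    # M step
    a_new <- a; b_new <- b
    for (j in seq_len(p)) {
      fit <- optim(c(a[j], b[j]), item_obj, gr = item_grad,
                   rbar = rbar[j, ], nbar = nbar,
                   method = "L-BFGS-B", lower = lower, upper = upper)
      a_new[j] <- fit$par[1]; b_new[j] <- fit$par[2]
    }
    delta <- max(abs(c(a_new - a, b_new - b)))
    a <- a_new; b <- b_new
    if (delta < tol_param || (cycle > 1 && ll - ll_prev < tol_loglik)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  structure(list(
    params = data.frame(id = colnames(X), a = a, b = b, c = fixed_c,
                        stringsAsFactors = FALSE),
    loglik_trace = trace, converged = converged, n_cycles = cycle,
    n = n, n_nodes = n_nodes, range = range, call = match.call()),
    class = "mist_3pl")
}

#' @export
print.mist_3pl <- function(x, ...) {
  cat(sprintf("<mist_3pl> %d items, n = %d, c fixed at %.2g\n",
              nrow(x$params), x$n, x$params$c[1]))
  cat(sprintf("  EM %s in %d cycle(s); marginal logLik %.3f\n",
              if (x$converged) "converged" else "did NOT converge",
              x$n_cycles, tail(x$loglik_trace, 1)))
  invisible(x)
}

#' @export
summary.mist_3pl <- function(object, ...) {
  cat(sprintf("3PL calibration (marginal ML, EM), n = %d respondents\n", object$n))
  cat(sprintf("  %s after %d cycles, final logLik %.3f\n",
              if (object$converged) "converged" else "not converged",
              object$n_cycles, tail(object$loglik_trace, 1)))
  print(transform(object$params, a = round(a, 3), b = round(b, 3)))
  invisible(object)
}

#' @export
coef.mist_3pl <- function(object, ...) {
  m <- as.matrix(object$params[, c("a", "b", "c")])
  rownames(m) <- object$params$id
  m
}

#' @export
logLik.mist_3pl <- function(object, ...) {
  structure(tail(object$loglik_trace, 1),
            df = 2L * nrow(object$params), class = "logLik")
}

#' @export
plot.mist_3pl <- function(x, theta = seq(-4, 4, length.out = 161), ...) {
  P <- vapply(seq_len(nrow(x$params)), function(j)
    icc_3pl(theta, x$params$a[j], x$params$b[j], x$params$c[j]),
    numeric(length(theta)))
  matplot(theta, P, type = "l", lty = 1, xlab = expression(theta),
          ylab = "P(correct)", main = "Item trace lines", ...)
  abline(h = (1 + x$params$c[1]) / 2, lty = 3)
  invisible(x)
}

#' Differential item functioning via anchored likelihood-ratio tests
#'
#' For each item, compares a model with group-specific discrimination and
#' difficulty against a model with shared parameters (df = 2), with all
#' other items anchored at their pooled calibration values and a
#' standard-normal trait prior in each group. Items are flagged at `alpha`
#' (uncorrected, as is conventional for DIF screens).
#'
#' @param data complete 0/1 matrix, respondents x items.
#' @param group a length-`nrow(data)` vector with exactly two distinct
#'   values. For a continuous covariate, dichotomize first (e.g., a median
#'   split).
#' @param alpha flagging level.
#' @param ... passed to [calibrate_3pl_em()] for the pooled fit.
#' @return A data frame of class `mist_dif` with columns `id`, `chi2`, `df`,
#'   `p`, `flagged`.
#' @export
dif_likelihood_ratio <- function(data, group, alpha = 0.05, ...) {
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("item_", seq_len(ncol(X)))
  group <- as.factor(group)
  if (nlevels(group) != 2) mist_stop("group_error",
    "DIF analysis needs exactly two groups")
  if (min(table(group)) < 100) mist_warn("small_n", paste0(
    "smallest group has ", min(table(group)),
    " respondents; DIF screening is recommended with >= 100 per group"))
  pooled <- calibrate_3pl_em(X, ...)
  params <- pooled$params
  q <- .quad(pooled$n_nodes, pooled$range)
  K <- length(q$nodes)
  cc <- params$c[1]
  g1 <- group == levels(group)[1]

  # per-respondent log-likelihood over nodes for all items except j
  logP <- vapply(seq_len(ncol(X)), function(j)
    .icc_logp(q$nodes, params$a[j], params$b[j], cc), numeric(K))
  logQ <- vapply(seq_len(ncol(X)), function(j)
    .icc_logq(q$nodes, params$a[j], params$b[j], cc), numeric(K))
  full_lw <- X %*% t(logP) + (1 - X) %*% t(logQ)

  marg <- function(lw_fixed, xj, par) {
    lw <- lw_fixed + outer(xj, .icc_logp(q$nodes, par[1], par[2], cc)) +
      outer(1 - xj, .icc_logq(q$nodes, par[1], par[2], cc))
    lw <- sweep(lw, 2, log(q$weights), `+`)
    m <- apply(lw, 1, max)
    sum(m + log(rowSums(exp(lw - m))))
  }
  lower <- c(0.05, pooled$range[1]); upper <- c(10, pooled$range[2])
  res <- lapply(seq_len(ncol(X)), function(j) {
    lw_fixed <- full_lw - (X[, j, drop = FALSE] %*% t(logP[, j, drop = FALSE]) +
                           (1 - X[, j, drop = FALSE]) %*% t(logQ[, j, drop = FALSE]))
    start <- c(params$a[j], params$b[j])
    f_equal <- optim(start, function(par) -marg(lw_fixed, X[, j], par),
                     method = "L-BFGS-B", lower = lower, upper = upper)
    f_g1 <- optim(start, function(par) -marg(lw_fixed[g1, , drop = FALSE], X[g1, j], par),
                  method = "L-BFGS-B", lower = lower, upper = upper)
    f_g2 <- optim(start, function(par) -marg(lw_fixed[!g1, , drop = FALSE], X[!g1, j], par),
                  method = "L-BFGS-B", lower = lower, upper = upper)
    chi2 <- max(0, 2 * (f_equal$value - f_g1$value - f_g2$value))
    data.frame(id = colnames(X)[j], chi2 = chi2, df = 2L,
               p = pchisq(chi2, df = 2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$flagged <- out$p < alpha
  class(out) <- c("mist_dif", "data.frame")
  out
}
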