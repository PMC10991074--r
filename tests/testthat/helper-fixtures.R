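# shared fixture builders (all generated in code, seeded per call)

# the answer key of a bank as a named label vector
bank_key <- function(bank) setNames(bank$items$veracity, bank$items$id)

# binary data from a simple-structure factor model: one block per factor,
# dichotomized at per-item thresholds
sim_factor_binary <- function(n, sizes, loadings, seed, phi = 0,
                              tau_range = c(-0.5, 0.5)) {
  set.seed(seed)
  K <- length(sizes)
  fac <- rep(seq_len(K), sizes)
  p <- length(fac)
  Th <- matrix(rnorm(n * K), n, K)
  if (phi != 0 && K > 1) {
    g <- rnorm(n)
    Th <- sqrt(phi) * g + sqrt(1 - phi) * Th
  }
  lam <- if (length(loadings) == 1) rep(loadings, p) else
    rep(loadings, length.out = p)
  tau <- runif(p, tau_range[1], tau_range[2])
  lat <- vapply(seq_len(p), function(j)
    lam[j] * Th[, fac[j]] + sqrt(1 - lam[j]^2) * rnorm(n), numeric(n))
  X <- (lat > matrix(tau, n, p, byrow = TRUE)) + 0L
  colnames(X) <- paste0("it", seq_len(p))
  list(X = X, factor = fac, lambda = lam, theta = Th)
}

# data simulated directly from known 3PL parameters
sim_3pl_binary <- function(n, a, b, seed, c = 0.5) {
  set.seed(seed)
  th <- rnorm(n)
  X <- vapply(seq_along(a), function(j)
    rbinom(n, 1, icc_3pl(th, a[j], b[j], c)), numeric(n))
  colnames(X) <- paste0("it", seq_along(a))
  list(X = X, theta = th)
}
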