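## Exploratory graph analysis: regularized partial-correlation networks
## (graphical lasso + EBIC model selection), Walktrap community detection,
## network loadings, redundancy (weighted topological overlap), parametric
## bootstrap stability, and entropy-based fit (TEFI).

# graphical lasso by block coordinate descent (Friedman et al. algorithm):
# returns the precision matrix Theta for penalty lambda (diagonal
# unpenalized). lambda = 0 falls back to the plain inverse.
.glasso <- function(S, lambda, max_iter = 100, tol = 1e-5,
                    W_init = NULL, B_init = NULL) {
  p <- ncol(S)
  if (lambda <= 0) {
    Theta <- solve(S)
    return(list(Theta = Theta, W = S, B = NULL))
  }
  W <- if (is.null(W_init)) S + diag(lambda, p) else W_init
  B <- if (is.null(B_init)) matrix(0, p - 1, p) else B_init
  off <- abs(S); diag(off) <- 0
  thr <- tol * max(mean(off), 1e-12)
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- seq_len(p)[-j]
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- B[, j]
      # lasso by coordinate descent on 0.5 b'W11 b - s12'b + lambda|b|_1
      for (cd in seq_len(50)) {
        delta <- 0
        for (k in seq_len(p - 1)) {
          resid <- s12[k] - sum(W11[k, ] * beta) + W11[k, k] * beta[k]
          bk <- sign(resid) * max(abs(resid) - lambda, 0) / W11[k, k]
          delta <- max(delta, abs(bk - beta[k]))
          beta[k] <- bk
        }
        if (delta < 1e-7) break
      }
      B[, j] <- beta
      w12 <- drop(W11 %*% beta)
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (mean(abs(W - W_old)) < thr) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- seq_len(p)[-j]
    theta22 <- 1 / (W[j, j] - sum(W[idx, j] * B[, j]))
    Theta[j, j] <- theta22
    Theta[idx, j] <- -B[, j] * theta22
  }
  Theta <- (Theta + t(Theta)) / 2
  list(Theta = Theta, W = W, B = B)
}

.theta_to_pcor <- function(Theta) {
  d <- sqrt(diag(Theta))
  P <- -Theta / tcrossprod(d)
  diag(P) <- 0
  (P + t(P)) / 2
}

#' EBICglasso network estimation
#'
#' Estimates a Gaussian graphical model (sparse partial-correlation network)
#' by running the graphical lasso over a log-spaced penalty path from the
#' largest absolute off-diagonal correlation down to
#' `lambda_min_ratio` times it, scoring every solution with the extended
#' Bayesian information criterion
#' \deqn{EBIC = -2\ell + E \log n + 4\gamma E \log p} (E = edge count), and
#' returning the minimal-EBIC network.
#'
#' @param corr a `mist_corr` or positive-definite correlation matrix.
#' @param n sample size behind the correlation matrix (required if `corr`
#'   is a plain matrix without one).
#' @param gamma EBIC hyperparameter (0.5 is the conventional default; 0
#'   reduces to BIC).
#' @param n_lambda number of penalties on the path.
#' @param lambda_min_ratio smallest penalty as a fraction of the largest.
#' @return An object of class `mist_network`: list with
#'   `partial_correlations` (p x p, zero diagonal), `lambda_selected`,
#'   `ebic` (value at the selected penalty), `gamma`, `n`, `path` (data
#'   frame of lambda, edge count, EBIC over the path).
#' @export
estimate_network <- function(corr, n = NULL, gamma = 0.5, n_lambda = 100,
                             lambda_min_ratio = 0.01) {
  if (inherits(corr, "mist_corr")) {
    n <- n %||% corr$n
    S <- corr$values
  } else S <- as.matrix(corr)
  if (is.null(n) || is.na(n)) mist_stop("matrix_error",
    "sample size n is required for EBIC network selection")
  p <- ncol(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) mist_stop("matrix_error",
    "correlation matrix is not positive definite; smooth it first")
  off <- abs(S); diag(off) <- 0
  lam_max <- max(off)
  if (lam_max < 1e-10) {
    # independence: empty network at any penalty
    P <- matrix(0, p, p); dimnames(P) <- dimnames(S)
    return(structure(list(partial_correlations = P, lambda_selected = 0,
                          ebic = NA_real_, gamma = gamma, n = n,
                          path = NULL), class = "mist_network"))
  }
  lambdas <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                     length.out = n_lambda))
  best <- NULL
  path <- vector("list", n_lambda)
  W_prev <- NULL; B_prev <- NULL
  for (i in seq_along(lambdas)) {
    fit <- .glasso(S, lambdas[i], W_init = W_prev, B_init = B_prev)
    W_prev <- fit$W; B_prev <- fit$B
    Theta <- fit$Theta
    E <- sum(abs(Theta[upper.tri(Theta)]) > 1e-10)
    ll <- (n / 2) * (determinant(Theta, logarithm = TRUE)$modulus[1] -
                     sum(S * Theta))
    ebic <- -2 * ll + E * log(n) + 4 * gamma * E * log(p)
    path[[i]] <- data.frame(lambda = lambdas[i], edges = E, ebic = ebic)
    if (is.null(best) || ebic < best$ebic) {
      best <- list(Theta = Theta, lambda = lambdas[i], ebic = ebic)
    }
  }
  P <- .theta_to_pcor(best$Theta)
  P[abs(P) < 1e-10] <- 0
  dimnames(P) <- dimnames(S)
  structure(list(partial_correlations = P, lambda_selected = best$lambda,
                 ebic = best$ebic, gamma = gamma, n = n,
                 path = do.call(rbind, path)),
            class = "mist_network")
}

#' @export
print.mist_network <- function(x, ...) {
  E <- sum(abs(x$partial_correlations[upper.tri(x$partial_correlations)]) > 0)
  cat(sprintf("<mist_network> %d nodes, %d edges (lambda %.4f, EBIC %.1f, gamma %.2g, n %d)\n",
              ncol(x$partial_correlations), E, x$lambda_selected, x$ebic,
              x$gamma, x$n))
  invisible(x)
}

#' Walktrap community detection on a partial-correlation network
#'
#' Runs the Walktrap random-walk algorithm (via igraph) on the graph
#' weighted by absolute partial correlations. Singleton communities are
#' merged into the community to which the node has the greatest summed
#' connection strength.
#'
#' @param network a `mist_network` (or a symmetric weight matrix).
#' @param steps random-walk length (Walktrap's customary default is 4).
#' @return A list of class `mist_partition`: `membership` (named integer
#'   vector, labels 1..K) and `K`.
#' @export
detect_communities <- function(network, steps = 4) {
  W <- if (inherits(network, "mist_network")) network$partial_correlations else as.matrix(network)
  A <- abs(W); diag(A) <- 0
  if (all(A == 0)) mist_stop("no_structure",
    "empty network: no edges, the number of dimensions is undefined")
  ids <- colnames(A) %||% paste0("V", seq_len(ncol(A)))
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  wt <- igraph::cluster_walktrap(g, weights = igraph::E(g)$weight, steps = steps)
  mem <- igraph::membership(wt)
  # merge singletons into the strongest-connected community
  repeat {
    sizes <- table(mem)
    singles <- as.integer(names(sizes)[sizes == 1])
    if (length(singles) == 0 || length(sizes) == 1) break
    moved <- FALSE
    for (s in singles) {
      node <- which(mem == s)
      strengths <- vapply(setdiff(unique(mem), s), function(cm)
        sum(A[node, mem == cm]), 0)
      if (all(strengths == 0)) next  # isolated node keeps its own dimension
      target <- setdiff(unique(mem), s)[which.max(strengths)]
      mem[node] <- target
      moved <- TRUE
    }
    if (!moved) break
  }
  mem <- as.integer(factor(mem))  # relabel 1..K
  names(mem) <- ids
  structure(list(membership = mem, K = length(unique(mem))),
            class = "mist_partition")
}

#' @export
print.mist_partition <- function(x, ...) {
  cat(sprintf("<mist_partition> %d dimension(s): sizes %s\n", x$K,
              paste(table(x$membership), collapse = "/")))
  invisible(x)
}

#' Network loadings
#'
#' Splits each node's strength (the summed absolute weight of its edges)
#' between the detected dimensions: the raw loading of item i on dimension
#' d is the summed absolute weight of i's edges into d. Each dimension's
#' column is then standardized by the square root of the summed
#' within-dimension loadings of its own members, and the sign of the
#' dominant edge is restored. On this scale, loadings of about .15, .25 and
#' .35 correspond to low (.40), moderate (.55) and high (.70) factor
#' loadings.
#'
#' @param network a `mist_network`.
#' @param partition a `mist_partition` over the same nodes.
#' @param standardize return standardized (default) or raw loadings.
#' @return A p x K matrix of class `mist_loadings` with the partition
#'   attached as attribute `"partition"`.
#' @export
network_loadings <- function(network, partition, standardize = TRUE) {
  W <- if (inherits(network, "mist_network")) network$partial_correlations else as.matrix(network)
  mem <- partition$membership
  p <- ncol(W)
  ks <- sort(unique(mem))
  raw <- vapply(ks, function(d) rowSums(abs(W[, mem == d, drop = FALSE])), numeric(p))
  raw <- matrix(raw, nrow = p)
  sgn <- vapply(ks, function(d) {
    s <- rowSums(W[, mem == d, drop = FALSE])
    ifelse(s == 0, 1, sign(s))
  }, numeric(p))
  L <- raw
  if (standardize) {
    norms <- vapply(seq_along(ks), function(i)
      sqrt(sum(raw[mem == ks[i], i])), 0)
    norms[norms == 0] <- 1
    L <- sweep(raw, 2, norms, `/`)
  }
  L <- L * sgn
  rownames(L) <- names(mem)
  colnames(L) <- paste0("Dim", ks)
  structure(L, class = c("mist_loadings", "matrix"), partition = partition)
}

#' Unique variable analysis: redundancy by weighted topological overlap
#'
#' Flags item pairs whose weighted topological overlap (wTO) in the
#' partial-correlation network meets `threshold`, i.e. pairs that connect to
#' the rest of the network in nearly the same way (typically paraphrases of
#' the same headline). For each flagged pair the keep/drop suggestion
#' retains the item with the higher ratio of its main network loading to its
#' mean absolute cross-loading.
#'
#' @param network a `mist_network`.
#' @param loadings a `mist_loadings` (for the keep rule); computed from the
#'   network's Walktrap partition when omitted.
#' @param threshold minimum wTO to flag (0.25 is the method's recommended
#'   cut).
#' @return A list of class `mist_uva`: `wto` (p x p matrix) and `pairs`
#'   (data frame `item_i`, `item_j`, `wto`, `keep`, `drop`,
#'   `ratio_i`, `ratio_j`).
#' @export
uva_redundancy <- function(network, loadings = NULL, threshold = 0.25) {
  W <- network$partial_correlations
  A <- abs(W); diag(A) <- 0
  p <- ncol(A)
  ids <- colnames(A) %||% paste0("V", seq_len(p))
  k <- rowSums(A)
  num <- A %*% A + A
  den <- outer(k, k, pmin) + 1 - A
  wto <- num / den
  diag(wto) <- 0
  dimnames(wto) <- list(ids, ids)
  if (is.null(loadings)) {
    part <- tryCatch(detect_communities(network), mistkit_no_structure = function(e) NULL)
    loadings <- if (is.null(part)) NULL else network_loadings(network, part)
  }
  ratio <- function(i) {
    if (is.null(loadings)) return(NA_real_)
    mem <- attr(loadings, "partition")$membership
    own <- paste0("Dim", mem[i])
    main <- abs(loadings[i, own])
    cross <- abs(loadings[i, setdiff(colnames(loadings), own)])
    if (length(cross) == 0 || mean(cross) == 0) return(Inf)
    main / mean(cross)
  }
  pairs <- list()
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (wto[i, j] >= threshold) {
      ri <- ratio(i); rj <- ratio(j)
      keep_i <- is.na(rj) || (!is.na(ri) && ri >= rj)
      pairs[[length(pairs) + 1]] <- data.frame(
        item_i = ids[i], item_j = ids[j], wto = wto[i, j],
        ratio_i = ri, ratio_j = rj,
        keep = if (keep_i) ids[i] else ids[j],
        drop = if (keep_i) ids[j] else ids[i],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(wto = wto,
                 pairs = if (length(pairs)) do.call(rbind, pairs) else
                   data.frame(item_i = character(0), item_j = character(0),
                              wto = numeric(0), ratio_i = numeric(0),
                              ratio_j = numeric(0), keep = character(0),
                              drop = character(0)),
                 threshold = threshold),
            class = "mist_uva")
}

#' @export
print.mist_uva <- function(x, ...) {
  cat(sprintf("<unique variable analysis> %d redundant pair(s) at wTO >= %.2f\n",
              nrow(x$pairs), x$threshold))
  if (nrow(x$pairs)) print(transform(x$pairs, wto = round(wto, 3)))
  invisible(x)
}

#' Exploratory graph analysis
#'
#' The full EGA pipeline on a binary correctness matrix: tetrachoric
#' correlations (smoothed to positive definite), EBICglasso network
#' estimation, Walktrap community detection, network loadings, and the
#' total entropy fit index of the detected partition.
#'
#' @param data 0/1 matrix, respondents x items, or a `mist_corr` (then `n`
#'   is taken from it).
#' @param gamma,n_lambda passed to [estimate_network()].
#' @param steps passed to [detect_communities()].
#' @param n sample size when `data` is a correlation object.
#' @return A list of class `mist_ega`: `network`, `partition`,
#'   `network_loadings`, `tefi`, `correlation`.
#' @export
ega <- function(data, gamma = 0.5, n_lambda = 100, steps = 4, n = NULL) {
  if (inherits(data, "mist_corr")) {
    corr <- data
    n <- n %||% corr$n
  } else {
    X <- as.matrix(data)
    corr <- tetrachoric_matrix(X)
    n <- nrow(X)
  }
  net <- estimate_network(corr, n = n, gamma = gamma, n_lambda = n_lambda)
  part <- detect_communities(net, steps = steps)
  nl <- network_loadings(net, part)
  structure(list(network = net, partition = part, network_loadings = nl,
                 tefi = tefi(corr, part), correlation = corr),
            class = "mist_ega")
}

#' @export
print.mist_ega <- function(x, ...) {
  cat(sprintf("<mist_ega> %d dimension(s) (sizes %s), TEFI %.3f\n",
              x$partition$K, paste(table(x$partition$membership), collapse = "/"),
              x$tefi))
  print(x$network)
  invisible(x)
}

#' Total entropy fit index
#'
#' Von Neumann entropy-based relative fit of a dimension partition to a
#' correlation matrix. The entropy of a (sub)matrix is
#' \eqn{-\sum \tilde\lambda \log \tilde\lambda} over the eigenvalues of the
#' trace-normalized absolute correlation (sub)matrix; with total entropy
#' `H` and per-dimension entropies `H_i` over `K` dimensions,
#' \deqn{TEFI = (\bar H_i - H) + (H - \sum H_i) \sqrt K.}
#' Lower values indicate better fit; the index is invariant to relabeling
#' the dimensions and is used to compare competing partitions of the same
#' items.
#'
#' @param corr a `mist_corr` or correlation matrix.
#' @param partition a `mist_partition` (or membership vector) over the
#'   matrix's variables.
#' @return The TEFI value (scalar).
#' @export
tefi <- function(corr, partition) {
  R <- abs(.corr_values(corr))
  mem <- if (inherits(partition, "mist_partition")) partition$membership else as.integer(partition)
  stopifnot(length(mem) == ncol(R))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) mist_stop("matrix_error",
    "correlation matrix is not positive semi-definite")
  H <- .vn_entropy(R)
  ks <- unique(mem)
  Hi <- vapply(ks, function(d) .vn_entropy(R[mem == d, mem == d, drop = FALSE]), 0)
  (mean(Hi) - H) + (H - sum(Hi)) * sqrt(length(ks))
}

.vn_entropy <- function(M) {
  M <- as.matrix(M)
  lam <- eigen(M / sum(diag(M)), symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-12]
  -sum(lam * log(lam))
}

#' Bootstrap exploratory graph analysis
#'
#' Parametric bootstrap of the EGA pipeline: `n_boot` multivariate-normal
#' replicates of size n are simulated from the smoothed empirical
#' correlation matrix, each re-estimated (Pearson correlations, EBICglasso,
#' Walktrap), and each replicate's dimensions are aligned to the empirical
#' partition by maximal Jaccard overlap (ties broken by larger intersection,
#' then lower label). Item stability is the proportion of replicates that
#' place an item in its aligned empirical dimension; structural consistency
#' is the proportion of replicates in which an empirical dimension's item
#' set is reproduced exactly.
#'
#' Replicates are continuous even when the empirical data are binary; this
#' keeps the bootstrap cheap and mirrors the smoothed latent correlation
#' structure rather than the binary margins.
#'
#' @param data 0/1 matrix, respondents x items.
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed.
#' @param gamma,n_lambda,steps passed to the pipeline.
#' @return A list of class `mist_bootega`: `empirical` (the `mist_ega` of
#'   the observed data), `n_dims` (replicate dimension counts),
#'   `median_dims`, `ci` (2.5/97.5 percentiles), `item_stability`,
#'   `structural_consistency`, `n_boot`, `n_failed`.
#' @export
boot_ega <- function(data, n_boot = 500, seed = NULL, gamma = 0.5,
                     n_lambda = 40, steps = 4) {
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  emp <- ega(X, gamma = gamma, n_lambda = n_lambda, steps = steps)
  R <- emp$correlation$values
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    e <- eigen(R, symmetric = TRUE)
    ch <- diag(sqrt(pmax(e$values, 1e-8))) %*% t(e$vectors)
  }
  if (!is.null(seed)) set.seed(seed)
  emp_mem <- emp$partition$membership
  emp_sets <- split(names(emp_mem), emp_mem)
  in_dim <- matrix(0, nrow = p, ncol = 0)
  placed <- matrix(NA, p, n_boot, dimnames = list(names(emp_mem), NULL))
  exact <- matrix(NA, length(emp_sets), n_boot,
                  dimnames = list(names(emp_sets), NULL))
  n_dims <- rep(NA_integer_, n_boot)
  n_failed <- 0L
  for (bidx in seq_len(n_boot)) {
    Z <- matrix(rnorm(n * p), n, p) %*% ch
    colnames(Z) <- colnames(R)
    res <- tryCatch({
      Rb <- smooth_corr(cor(Z), kind = "pearson", n = n)
      net <- estimate_network(Rb, n = n, gamma = gamma, n_lambda = n_lambda)
      detect_communities(net, steps = steps)
    }, error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    n_dims[bidx] <- res$K
    rep_sets <- split(names(res$membership), res$membership)
    # align each replicate dimension to the empirical dimension with
    # maximal Jaccard overlap
    for (rs_lab in names(rep_sets)) {
      rs <- rep_sets[[rs_lab]]
      jac <- vapply(emp_sets, function(es)
        length(intersect(rs, es)) / length(union(rs, es)), 0)
      inter <- vapply(emp_sets, function(es) length(intersect(rs, es)), 0)
      ord <- order(-jac, -inter, as.integer(names(emp_sets)))
      aligned <- names(emp_sets)[ord[1]]
      if (jac[ord[1]] > 0) {
        placed[rs, bidx] <- aligned
        if (setequal(rs, emp_sets[[aligned]])) exact[aligned, bidx] <- TRUE
      }
    }
    exact[is.na(exact[, bidx]), bidx] <- FALSE
  }
  ok <- !is.na(n_dims)
  if (n_failed > 0.1 * n_boot) mist_warn("boot_failures", paste0(
    n_failed, " of ", n_boot, " bootstrap replicates failed"))
  item_stab <- vapply(seq_len(p), function(i)
    mean(placed[i, ok] == as.character(emp_mem[i])), 0)
  names(item_stab) <- names(emp_mem)
  struct <- rowMeans(exact[, ok, drop = FALSE])
  structure(list(empirical = emp, n_dims = n_dims[ok],
                 median_dims = median(n_dims[ok]),
                 ci = quantile(n_dims[ok], c(0.025, 0.975), names = FALSE),
                 item_stability = item_stab,
                 structural_consistency = struct,
                 n_boot = n_boot, n_failed = n_failed),
            class = "mist_bootega")
}

#' @export
print.mist_bootega <- function(x, ...) {
  cat(sprintf("<bootEGA> %d replicates (%d failed): median %.0f dimension(s), 95%% CI [%.2f, %.2f]\n",
              x$n_boot, x$n_failed, x$median_dims, x$ci[1], x$ci[2]))
  cat(sprintf("  item stability: min %.2f, median %.2f\n",
              min(x$item_stability), median(x$item_stability)))
  cat("  structural consistency:",
      paste(sprintf("dim %s = %.2f", names(x$structural_consistency),
                    x$structural_consistency), collapse = ", "), "\n")
  invisible(x)
}
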