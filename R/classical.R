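## Classical test theory engine: tetrachoric correlations, parallel analysis,
## exploratory factor analysis, and reliability coefficients for binary
## correctness matrices.

# 16-point Gauss-Legendre nodes/weights on [-1, 1]
.gl16 <- list(
  x = c(-0.9894009349916499, -0.9445750230732326, -0.8656312023878318,
        -0.7554044083550030, -0.6178762444026438, -0.4580167776572274,
        -0.2816035507792589, -0.0950125098376374,  0.0950125098376374,
         0.2816035507792589,  0.4580167776572274,  0.6178762444026438,
         0.7554044083550030,  0.8656312023878318,  0.9445750230732326,
         0.9894009349916499),
  w = c(0.0271524594117541, 0.0622535239386479, 0.0951585116824928,
        0.1246289712555339, 0.1495959888165767, 0.1691565193950025,
        0.1826034150449236, 0.1894506104550685, 0.1894506104550685,
        0.1826034150449236, 0.1691565193950025, 0.1495959888165767,
        0.1246289712555339, 0.0951585116824928, 0.0622535239386479,
        0.0271524594117541))

# standard bivariate normal CDF P(Z1 <= h, Z2 <= k; rho) by Gauss-Legendre
# quadrature of the Drezner-Wesolowsky single integral over the correlation
.pbvn <- function(h, k, rho) {
  if (abs(rho) < 1e-12) return(pnorm(h) * pnorm(k))
  # panelled quadrature keeps accuracy near |rho| -> 1
  n_panel <- if (abs(rho) > 0.9) 4L else 1L
  edges <- seq(0, rho, length.out = n_panel + 1L)
  integral <- 0
  for (i in seq_len(n_panel)) {
    mid <- (edges[i] + edges[i + 1]) / 2
    half <- (edges[i + 1] - edges[i]) / 2
    t <- mid + half * .gl16$x
    f <- exp(-(h^2 - 2 * h * k * t + k^2) / (2 * (1 - t^2))) / sqrt(1 - t^2)
    integral <- integral + half * sum(.gl16$w * f)
  }
  pnorm(h) * pnorm(k) + integral / (2 * pi)
}

# ML tetrachoric from a 2x2 table given thresholds; counts in order
# (x=0,y=0), (x=0,y=1), (x=1,y=0), (x=1,y=1)
.tetra_ml <- function(n00, n01, n10, n11, tol = 1e-5) {
  if (min(n00, n01, n10, n11) == 0) {  # continuity correction for empty cells
    n00 <- n00 + 0.5; n01 <- n01 + 0.5; n10 <- n10 + 0.5; n11 <- n11 + 0.5
  }
  n <- n00 + n01 + n10 + n11
  tau1 <- qnorm((n00 + n01) / n)   # P(x = 0)
  tau2 <- qnorm((n00 + n10) / n)
  p1 <- pnorm(tau1); p2 <- pnorm(tau2)
  negll <- function(rho) {
    p00 <- .pbvn(tau1, tau2, rho)
    p00 <- min(max(p00, 1e-12), min(p1, p2) - 1e-12)
    p01 <- p1 - p00; p10 <- p2 - p00; p11 <- 1 - p1 - p2 + p00
    if (p01 <= 0 || p10 <= 0 || p11 <= 0) return(1e10)
    -(n00 * log(p00) + n01 * log(p01) + n10 * log(p10) + n11 * log(p11))
  }
  optimize(negll, c(-0.9995, 0.9995), tol = tol)$minimum
}

#' Tetrachoric correlation of two binary vectors
#'
#' Maximum-likelihood estimate of the latent bivariate-normal correlation
#' underlying a 2x2 table of dichotomous responses. Thresholds are fixed at
#' the observed margins; the correlation is found by bounded scalar search
#' on the table likelihood. Tables with an empty cell receive a +0.5
#' continuity correction on all cells before estimation.
#'
#' @param x,y binary (0/1) vectors of equal length.
#' @return The estimated correlation in (-1, 1).
#' @export
tetrachoric <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    mist_stop("degenerate_item", "tetrachoric needs both outcomes in each column")
  }
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  .tetra_ml(n00, n01, n10, n11)
}

#' Tetrachoric correlation matrix
#'
#' Pairwise ML tetrachoric correlations of a binary data matrix. If the
#' resulting matrix is not positive definite it is eigen-clipped (minimum
#' eigenvalue 1e-6), rescaled to unit diagonal, and flagged as smoothed.
#'
#' @param data 0/1 matrix or data frame, respondents x items.
#' @return An object of class `mist_corr`: list with `values` (p x p
#'   matrix), `kind = "tetrachoric"`, `smoothed` flag, and `n`.
#' @export
tetrachoric_matrix <- function(data) {
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  p <- ncol(X)
  cm <- colMeans(X, na.rm = TRUE)
  const <- cm %in% c(0, 1)
  if (any(const)) mist_stop("degenerate_item", paste0(
    "constant column(s): ", paste(colnames(X)[const] %||% which(const), collapse = ", ")))
  R <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      R[i, j] <- R[j, i] <- tetrachoric(X[, i], X[, j])
    }
  }
  dimnames(R) <- list(colnames(X), colnames(X))
  smooth_corr(R, kind = "tetrachoric", n = nrow(X))
}

#' @param R a symmetric correlation matrix.
#' @param kind correlation kind label.
#' @param n sample size behind the matrix.
#' @param min_eigen smallest admissible eigenvalue before clipping.
#' @rdname tetrachoric_matrix
#' @export
smooth_corr <- function(R, kind = "pearson", n = NA, min_eigen = 1e-6) {
  dn <- dimnames(R)
  e <- eigen(R, symmetric = TRUE)
  smoothed <- FALSE
  if (min(e$values) < min_eigen) {
    vals <- pmax(e$values, min_eigen)
    R <- e$vectors %*% diag(vals) %*% t(e$vectors)
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
    smoothed <- TRUE
  }
  R <- (R + t(R)) / 2
  diag(R) <- 1
  dimnames(R) <- dn
  structure(list(values = R, kind = kind, smoothed = smoothed, n = n),
            class = "mist_corr")
}

.corr_values <- function(x) {
  if (inherits(x, "mist_corr")) x$values else as.matrix(x)
}

#' @export
print.mist_corr <- function(x, ...) {
  cat(sprintf("<mist_corr> %d x %d %s matrix%s%s\n", nrow(x$values), ncol(x$values),
              x$kind, if (x$smoothed) " (smoothed)" else "",
              if (!is.na(x$n)) paste0(", n = ", x$n) else ""))
  invisible(x)
}

#' Parallel analysis for factor retention
#'
#' Compares the descending eigenvalues of the observed tetrachoric matrix
#' with per-rank 95th percentiles of eigenvalues from `n_sim` null datasets.
#' Null datasets are column-wise independent permutations of the observed
#' data, which preserves the binary margins and hence the tetrachoric
#' sampling behaviour (a Gaussian null would not). The number of factors
#' retained is the length of the leading run of observed eigenvalues above
#' their per-rank threshold.
#'
#' @param data 0/1 matrix, respondents x items.
#' @param n_sim number of null datasets.
#' @param quantile per-rank null quantile.
#' @param seed optional seed for the permutations.
#' @return A list of class `mist_parallel`: `observed_eigenvalues`,
#'   `sim_quantiles`, `n_retained`, `n_sim`.
#' @export
parallel_analysis <- function(data, n_sim = 500, quantile = 0.95, seed = NULL) {
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  obs <- sort(eigen(tetrachoric_matrix(X)$values, symmetric = TRUE,
                    only.values = TRUE)$values, decreasing = TRUE)
  if (!is.null(seed)) set.seed(seed)
  csums <- colSums(X)
  # under column permutations margins are fixed, so a pair's tetrachoric
  # depends only on its n11 count: memoize on (i, j, n11)
  cache <- new.env(parent = emptyenv())
  tet_cached <- function(i, j, n11) {
    key <- paste(csums[i], csums[j], n11, sep = "_")
    v <- cache[[key]]
    if (is.null(v)) {
      n10 <- csums[i] - n11; n01 <- csums[j] - n11
      v <- .tetra_ml(n - n11 - n10 - n01, n01, n10, n11, tol = 1e-4)
      cache[[key]] <- v
    }
    v
  }
  sim_eigs <- matrix(NA_real_, n_sim, p)
  for (s in seq_len(n_sim)) {
    Xs <- apply(X, 2, sample)
    cross <- crossprod(Xs)
    R <- diag(p)
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      R[i, j] <- R[j, i] <- tet_cached(i, j, cross[i, j])
    }
    sim_eigs[s, ] <- sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
                          decreasing = TRUE)
  }
  thresh <- apply(sim_eigs, 2, quantile, probs = quantile, names = FALSE)
  above <- obs > thresh
  n_retained <- if (above[1]) which.min(c(above, FALSE)) - 1L else 0L
  structure(list(observed_eigenvalues = obs, sim_quantiles = thresh,
                 n_retained = as.integer(n_retained), n_sim = n_sim,
                 quantile = quantile),
            class = "mist_parallel")
}

#' @export
print.mist_parallel <- function(x, ...) {
  cat(sprintf("<parallel analysis> %d factor(s) retained (%d null datasets, %.2f quantile)\n",
              x$n_retained, x$n_sim, x$quantile))
  k <- min(6, length(x$observed_eigenvalues))
  cat("  observed:", paste(round(x$observed_eigenvalues[1:k], 2), collapse = " "), "...\n")
  cat("  null q:  ", paste(round(x$sim_quantiles[1:k], 2), collapse = " "), "...\n")
  invisible(x)
}

#' Exploratory factor analysis on binary items
#'
#' Principal-axis factoring (`method = "paf"`, iterated communalities
#' started from squared multiple correlations) or unweighted least squares
#' (`method = "uls"`, direct minimization of squared residuals over
#' uniquenesses) on the tetrachoric correlation matrix, optionally followed
#' by varimax rotation with Kaiser normalization. Rotation leaves
#' communalities unchanged.
#'
#' @param data 0/1 matrix, or a `mist_corr`/correlation matrix.
#' @param k number of factors (`k < p`).
#' @param method `"paf"` or `"uls"`.
#' @param rotation `"varimax"` or `"none"`.
#' @param max_iter,tol PAF iteration controls (max change in communality).
#' @return A list of class `mist_efa`: `loadings` (p x k), `communalities`,
#'   `uniquenesses`, `rotation`, `method`, `converged`, `heywood`, `rmsr`
#'   (off-diagonal root-mean-square residual).
#' @export
efa <- function(data, k, method = c("paf", "uls"), rotation = c("varimax", "none"),
                max_iter = 100, tol = 1e-3) {
  method <- match.arg(method)
  rotation <- match.arg(rotation)
  if (inherits(data, "mist_corr") || (is.matrix(data) && isTRUE(all.equal(unname(diag(data)), rep(1, ncol(data)))))) {
    R <- .corr_values(data)
  } else {
    R <- tetrachoric_matrix(data)$values
  }
  p <- ncol(R)
  stopifnot(k >= 1, k < p)
  smc <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) {
    r2 <- R; diag(r2) <- 0; apply(abs(r2), 1, max)^2
  })
  smc <- pmin(pmax(smc, 0.05), 0.995)
  heywood <- FALSE
  converged <- TRUE

  principal_k <- function(Rh) {
    e <- eigen(Rh, symmetric = TRUE)
    vals <- pmax(e$values[1:k], 0)
    L <- e$vectors[, 1:k, drop = FALSE] %*% diag(sqrt(vals), k)
    L
  }
  if (method == "paf") {
    h2 <- smc
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      Rh <- R; diag(Rh) <- h2
      L <- principal_k(Rh)
      h2_new <- rowSums(L^2)
      if (any(h2_new > 1)) { heywood <- TRUE; h2_new <- pmin(h2_new, 1) }
      if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; converged <- TRUE; break }
      h2 <- h2_new
    }
    Rh <- R; diag(Rh) <- h2
    L <- principal_k(Rh)
  } else {
    obj <- function(u) {
      Rh <- R; diag(Rh) <- 1 - u
      e <- eigen(Rh, symmetric = TRUE, only.values = TRUE)$values
      sum(e[(k + 1):p]^2)
    }
    fit <- optim(1 - smc, obj, method = "L-BFGS-B",
                 lower = rep(0.005, p), upper = rep(1, p))
    converged <- fit$convergence == 0
    Rh <- R; diag(Rh) <- 1 - fit$par
    L <- principal_k(Rh)
  }
  h2 <- pmin(rowSums(L^2), 1)
  if (any(rowSums(L^2) > 1 + 1e-8)) heywood <- TRUE
  if (rotation == "varimax" && k > 1) {
    rot <- stats::varimax(L, normalize = TRUE)
    L <- unclass(rot$loadings)
  }
  # orient each factor so its largest loading is positive
  for (j in seq_len(k)) if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  rownames(L) <- colnames(R)
  colnames(L) <- paste0("F", seq_len(k))
  resid <- R - tcrossprod(L); diag(resid) <- 0
  rmsr <- sqrt(sum(resid^2) / (p * (p - 1)))
  structure(list(loadings = L, communalities = rowSums(L^2),
                 uniquenesses = 1 - rowSums(L^2), rotation = rotation,
                 method = method, converged = converged, heywood = heywood,
                 rmsr = rmsr),
            class = "mist_efa")
}

#' @export
print.mist_efa <- function(x, ...) {
  cat(sprintf("<mist_efa> %d factors (%s, %s rotation)%s, RMSR %.3f\n",
              ncol(x$loadings), toupper(x$method), x$rotation,
              if (x$heywood) ", Heywood case clipped" else "", x$rmsr))
  print(round(x$loadings, 2))
  invisible(x)
}

#' Communalities implied by 3PL discriminations
#'
#' Converts each item's 3PL discrimination to a normal-metric factor loading
#' \eqn{\lambda = (a/1.702)/\sqrt{1 + (a/1.702)^2}} and returns the implied
#' communality \eqn{h^2 = \lambda^2}. This is the communality screen used
#' after 3PL calibration in the item-selection decision tree.
#'
#' @param params item parameters with column `a` (e.g. from
#'   [calibrate_3pl_em()] or a bank).
#' @return A named numeric vector of communalities.
#' @export
communalities_from_3pl <- function(params) {
  if (inherits(params, "mist_3pl")) params <- params$params
  if (inherits(params, "mist_bank")) params <- params$items
  params <- as.data.frame(params)
  if (!"a" %in% names(params) || any(is.na(params$a))) {
    mist_stop("missing_parameter", "discrimination 'a' required for every item")
  }
  lam <- (params$a / 1.702) / sqrt(1 + (params$a / 1.702)^2)
  setNames(lam^2, params$id %||% rownames(params))
}

#' Cronbach's alpha
#'
#' The covariance-formula alpha, `k/(k-1) * (1 - sum(var_i)/var_total)`; on
#' 0/1 items this is KR-20.
#'
#' @param data numeric matrix, respondents x items.
#' @return Alpha.
#' @export
cronbach_alpha <- function(data) {
  X <- as.matrix(data)
  k <- ncol(X)
  k / (k - 1) * (1 - sum(apply(X, 2, var)) / var(rowSums(X)))
}

#' Alpha-if-deleted pruning
#'
#' Iteratively removes the single item whose deletion raises Cronbach's
#' alpha by more than `delta`, recomputing after each removal, until no item
#' qualifies or fewer than 3 items remain (in which case pruning stops with
#' a warning). An item whose deletion would lower alpha is never removed.
#'
#' @param data 0/1 matrix, respondents x items.
#' @param delta minimum alpha improvement that triggers removal.
#' @return A list with `kept` (column names retained), `removed` (in
#'   removal order), `trace` (data frame of per-step alpha values), `alpha`
#'   (final).
#' @export
alpha_if_deleted_prune <- function(data, delta = 0.001) {
  X <- as.matrix(data)
  if (is.null(colnames(X))) colnames(X) <- paste0("item_", seq_len(ncol(X)))
  removed <- character(0)
  trace <- list()
  repeat {
    if (ncol(X) < 3) {
      mist_warn("pool_exhausted", "fewer than 3 items remain; pruning stopped")
      break
    }
    a0 <- cronbach_alpha(X)
    a_del <- vapply(seq_len(ncol(X)), function(j) cronbach_alpha(X[, -j, drop = FALSE]), 0)
    gain <- a_del - a0
    jmax <- which.max(gain)
    trace[[length(trace) + 1]] <- data.frame(
      step = length(trace) + 1L, alpha = a0,
      candidate = colnames(X)[jmax], gain = gain[jmax], stringsAsFactors = FALSE)
    if (gain[jmax] > delta) {
      removed <- c(removed, colnames(X)[jmax])
      X <- X[, -jmax, drop = FALSE]
    } else break
  }
  list(kept = colnames(X), removed = removed,
       trace = do.call(rbind, trace), alpha = cronbach_alpha(X))
}

# one-factor principal-axis loadings of a correlation submatrix
.block_loadings <- function(R, max_iter = 100, tol = 1e-5) {
  p <- ncol(R)
  if (p == 1) return(1)
  h2 <- {r2 <- R; diag(r2) <- 0; pmin(pmax(apply(abs(r2), 1, max), 0.05), 0.99)}
  for (it in seq_len(max_iter)) {
    Rh <- R; diag(Rh) <- h2
    e <- eigen(Rh, symmetric = TRUE)
    lam <- e$vectors[, 1] * sqrt(max(e$values[1], 0))
    if (sum(lam) < 0) lam <- -lam
    h2_new <- pmin(lam^2, 1)
    if (max(abs(h2_new - h2)) < tol) break
    h2 <- h2_new
  }
  lam
}

#' Reliability report for a two-factor binary scale
#'
#' Computes the standard internal-consistency summary for a scale with two
#' facets (e.g. real-news and fake-news detection): inter-item correlation
#' (IIC) range, corrected item-total correlation (ITC) range, Cronbach's
#' alpha, McDonald's omega for the general factor and the two group factors,
#' a per-factor variance decomposition, and (optionally) test-retest
#' correlation of total scores.
#'
#' Omegas come from a two-factor congeneric model with a higher-order
#' general factor, orthogonalized Schmid-Leiman style: within-factor
#' loadings are estimated by principal-axis factoring of each facet's
#' correlation block, the inter-facet correlation phi from the
#' cross-block correlations, and each item's general loading is
#' `lambda * sqrt(phi)` with group loading `lambda * sqrt(1 - phi)`. Then
#' `omega_g = (sum g)^2 / sum(R)` and each facet's omega is computed on its
#' own block.
#'
#' @param data 0/1 matrix, respondents x items.
#' @param factor_assignment vector (length p) of factor labels covering all
#'   items in exactly two groups.
#' @param retest optional second 0/1 matrix with the same columns, aligned
#'   to `data` by row names, for a test-retest correlation of total scores.
#' @param cor_method correlation used for the omega model: `"pearson"`
#'   (observed 0/1 scale, default) or `"tetrachoric"` (latent scale).
#' @return A list of class `mist_reliability` with fields `alpha`,
#'   `iic_min`, `iic_max`, `itc_min`, `itc_max`, `omega_g`, `omega_f` (named
#'   per factor), `phi`, `variance_decomposition`, `test_retest`.
#' @export
reliability_report <- function(data, factor_assignment, retest = NULL,
                               cor_method = c("pearson", "tetrachoric")) {
  cor_method <- match.arg(cor_method)
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  p <- ncol(X)
  stopifnot(length(factor_assignment) == p)
  fac <- as.factor(factor_assignment)
  if (nlevels(fac) != 2) mist_stop("parse_error",
    "reliability_report expects a two-factor assignment")
  Rp <- cor(X)
  off <- Rp[upper.tri(Rp)]
  total <- rowSums(X)
  itc <- vapply(seq_len(p), function(j) cor(X[, j], total - X[, j]), 0)
  R <- if (cor_method == "tetrachoric") tetrachoric_matrix(X)$values else Rp

  lam <- numeric(p)
  for (lv in levels(fac)) {
    idx <- which(fac == lv)
    lam[idx] <- .block_loadings(R[idx, idx, drop = FALSE])
  }
  i1 <- which(fac == levels(fac)[1]); i2 <- which(fac == levels(fac)[2])
  cross <- R[i1, i2, drop = FALSE] / tcrossprod(lam[i1], lam[i2])
  phi <- min(max(mean(cross), 0), 0.999)
  g <- lam * sqrt(phi)
  s <- lam * sqrt(1 - phi)
  omega_g <- min(max(sum(g)^2 / sum(R), 0), 1)
  omega_f <- vapply(levels(fac), function(lv) {
    idx <- which(fac == lv)
    min(max((sum(g[idx])^2 + sum(s[idx])^2) / sum(R[idx, idx]), 0), 1)
  }, 0)

  # variance decomposition from a two-factor varimax solution
  ef <- efa(smooth_corr(R, kind = cor_method, n = nrow(X)), k = 2,
            method = "paf", rotation = "varimax")
  pct <- colSums(ef$loadings^2) / p
  share <- pct / sum(pct)

  test_retest <- NA_real_
  if (!is.null(retest)) {
    Y <- as.matrix(retest)
    if (!is.null(rownames(X)) && !is.null(rownames(Y))) {
      common <- intersect(rownames(X), rownames(Y))
      if (length(common) < 3) mist_stop("alignment_error",
        "fewer than 3 respondents shared between test and retest")
      test_retest <- cor(rowSums(X[common, , drop = FALSE]),
                         rowSums(Y[common, , drop = FALSE]))
    } else {
      if (nrow(Y) != nrow(X)) mist_stop("alignment_error",
        "retest matrix rows do not align with the test matrix")
      test_retest <- cor(total, rowSums(Y))
    }
  }
  structure(list(alpha = cronbach_alpha(X),
                 iic_min = min(off), iic_max = max(off),
                 itc_min = min(itc), itc_max = max(itc),
                 omega_g = omega_g, omega_f = omega_f, phi = phi,
                 loadings_general = g, loadings_group = s,
                 variance_decomposition = data.frame(
                   factor = colnames(ef$loadings),
                   pct_total_variance = pct, share_of_explained = share,
                   row.names = NULL),
                 test_retest = test_retest, cor_method = cor_method),
            class = "mist_reliability")
}

#' @export
print.mist_reliability <- function(x, ...) {
  cat(sprintf("<reliability> alpha %.3f | IIC [%.2f, %.2f] | ITC [%.2f, %.2f]\n",
              x$alpha, x$iic_min, x$iic_max, x$itc_min, x$itc_max))
  cat(sprintf("  omega_g %.3f | %s | phi %.3f (%s scale)\n",
              x$omega_g,
              paste(sprintf("omega_%s %.3f", names(x$omega_f), x$omega_f), collapse = " | "),
              x$phi, x$cor_method))
  vd <- x$variance_decomposition
  cat(sprintf("  variance: %s\n", paste(
    sprintf("%s %.0f%% of total (%.0f%% of explained)", vd$factor,
            100 * vd$pct_total_variance, 100 * vd$share_of_explained), collapse = "; ")))
  if (!is.na(x$test_retest)) cat(sprintf("  test-retest r = %.3f\n", x$test_retest))
  invisible(x)
}
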