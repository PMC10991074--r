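#' Respondent and simulation settings
#'
#' `respondent_model()` describes the generating model for synthetic
#' respondents: a higher-order two-factor 3PL. A general veracity-
#' discernment trait `theta_V ~ N(0,1)` drives the two first-order traits,
#' `theta_r = gamma_r * theta_V + sqrt(1 - gamma_r^2) * eps` (real-news
#' detection) and likewise `theta_f` (fake-news detection). A response-bias
#' mixture overlays yea/nay-saying: with probability `bias_tau` a response
#' is bias-driven rather than trait-driven, in which case it is labeled
#' `"fake"` with probability `bias_pi` (so `bias_pi` near 1 is a distrust
#' profile, near 0 a naivete profile).
#'
#' @param gamma_r,gamma_f higher-order loadings in \[0, 1\].
#' @param bias_tau probability a response is bias-driven.
#' @param bias_pi probability a bias-driven response is `"fake"`.
#' @param bias_level `"response"` (each response independently bias-driven,
#'   default) or `"respondent"` (each respondent is entirely bias-driven
#'   with probability `bias_tau`).
#' @return A list of class `mist_respondent_model`.
#' @export
respondent_model <- function(gamma_r = 0.8, gamma_f = 0.8,
                             bias_tau = 0, bias_pi = 0.5,
                             bias_level = c("response", "respondent")) {
  stopifnot(gamma_r >= 0, gamma_r <= 1, gamma_f >= 0, gamma_f <= 1,
            bias_tau >= 0, bias_tau <= 1, bias_pi >= 0, bias_pi <= 1)
  structure(list(gamma_r = gamma_r, gamma_f = gamma_f, bias_tau = bias_tau,
                 bias_pi = bias_pi, bias_level = match.arg(bias_level)),
            class = "mist_respondent_model")
}

#' @param n number of respondents.
#' @param seed RNG seed (recorded in the output metadata).
#' @param id_prefix respondent id prefix.
#' @rdname respondent_model
#' @export
sim_config <- function(n, seed = 1L, id_prefix = "R") {
  stopifnot(n >= 1)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 id_prefix = id_prefix), class = "mist_sim_config")
}

#' Simulate respondents on an item bank
#'
#' Draws binary real/fake labels for `config$n` synthetic respondents on a
#' calibrated bank under the higher-order two-factor 3PL of
#' [respondent_model()]: a real item is labeled `"real"` with probability
#' `icc_3pl(theta_r; a, b, c)` and a fake item `"fake"` with probability
#' `icc_3pl(theta_f; a, b, c)`, with the bias mixture overriding individual
#' responses.
#'
#' @param bank a `mist_bank` whose items carry `a` and `b` (`c` defaults to
#'   0.5).
#' @param model a [respondent_model()].
#' @param config a [sim_config()].
#' @param thetas optional data frame with columns `theta_r` and `theta_f`
#'   (and optionally `theta_v`) fixing the latent traits instead of drawing
#'   them -- used for paired pre/post designs (e.g. an intervention that
#'   shifts `theta_f`) and for probing the generator at chosen trait
#'   levels. Must have `config$n` rows.
#' @return A list with `responses` (wide data frame: `respondent_id` + one
#'   `"real"`/`"fake"` column per item, ready for [score_matrix()]),
#'   `thetas` (data frame `theta_v`, `theta_r`, `theta_f`), and `meta`
#'   (model + seed).
#' @export
simulate_responses <- function(bank, model = respondent_model(), config,
                               thetas = NULL) {
  stopifnot(inherits(bank, "mist_bank"), inherits(config, "mist_sim_config"))
  items <- bank$items
  if (any(is.na(items$a)) || any(is.na(items$b))) {
    mist_stop("missing_parameter",
              "every bank item needs a and b to simulate responses")
  }
  items$c[is.na(items$c)] <- 0.5
  set.seed(config$seed)
  n <- config$n
  if (is.null(thetas)) {
    theta_v <- rnorm(n)
    theta_r <- model$gamma_r * theta_v + sqrt(1 - model$gamma_r^2) * rnorm(n)
    theta_f <- model$gamma_f * theta_v + sqrt(1 - model$gamma_f^2) * rnorm(n)
  } else {
    thetas <- as.data.frame(thetas)
    stopifnot(nrow(thetas) == n, all(c("theta_r", "theta_f") %in% names(thetas)))
    theta_r <- thetas$theta_r
    theta_f <- thetas$theta_f
    theta_v <- thetas$theta_v %||% (theta_r + theta_f) / 2
  }
  p <- nrow(items)
  lab <- matrix(NA_character_, n, p)
  if (model$bias_level == "respondent") {
    bias_resp <- runif(n) < model$bias_tau
  }
  for (j in seq_len(p)) {
    th <- if (items$veracity[j] == "real") theta_r else theta_f
    p_correct <- icc_3pl(th, items$a[j], items$b[j], items$c[j])
    correct <- runif(n) < p_correct
    lab[, j] <- ifelse(correct, items$veracity[j],
                       ifelse(items$veracity[j] == "real", "fake", "real"))
    biased <- if (model$bias_level == "respondent") bias_resp
              else runif(n) < model$bias_tau
    if (any(biased)) {
      lab[biased, j] <- ifelse(runif(sum(biased)) < model$bias_pi, "fake", "real")
    }
  }
  responses <- data.frame(respondent_id = paste0(config$id_prefix, seq_len(n)),
                          lab, stringsAsFactors = FALSE)
  names(responses) <- c("respondent_id", items$id)
  list(responses = responses,
       thetas = data.frame(respondent_id = responses$respondent_id,
                           theta_v = theta_v, theta_r = theta_r,
                           theta_f = theta_f, stringsAsFactors = FALSE),
       meta = list(model = model, seed = config$seed, bank = bank$name))
}

#' Item-pool specification
#'
#' Describes a synthetic item pool with planted structure for exercising the
#' selection and dimensionality machinery: `n_factors` content factors with
#' `items_per_factor` well-behaved items each (loadings drawn from
#' `loading_good`), plus `n_junk` pure-noise items, `n_crossloaded` items
#' loading on two factors at once, and `n_redundant_pairs` pairs sharing an
#' extra pair-specific minor factor.
#'
#' @param n_factors 2 or 4.
#' @param items_per_factor good items per factor.
#' @param loading_good range of main loadings for good items.
#' @param n_junk number of zero-loading junk items.
#' @param n_crossloaded number of items with a secondary loading drawn from
#'   `crossloading`.
#' @param crossloading range of secondary loadings for cross-loaded items.
#' @param n_redundant_pairs number of redundant item pairs.
#' @param redundant_loading loading on the pair-specific minor factor.
#' @param higher_order if `TRUE`, factor traits share a general factor with
#'   loading `gamma`.
#' @param gamma higher-order loading when `higher_order`.
#' @param tau_range item thresholds are drawn uniformly from this range
#'   (mimicking the published difficulty spread).
#' @return A list of class `mist_pool_spec`.
#' @export
pool_spec <- function(n_factors = 2, items_per_factor = 30,
                      loading_good = c(0.55, 0.80), n_junk = 0,
                      n_crossloaded = 0, crossloading = c(0.35, 0.45),
                      n_redundant_pairs = 0, redundant_loading = 0.45,
                      higher_order = FALSE, gamma = 0.7,
                      tau_range = c(-0.8, 0.8)) {
  stopifnot(n_factors >= 1, items_per_factor >= 1, n_junk >= 0,
            n_crossloaded >= 0, n_redundant_pairs >= 0,
            all(loading_good >= 0), all(loading_good < 1))
  structure(list(n_factors = n_factors, items_per_factor = items_per_factor,
                 loading_good = loading_good, n_junk = n_junk,
                 n_crossloaded = n_crossloaded, crossloading = crossloading,
                 n_redundant_pairs = n_redundant_pairs,
                 redundant_loading = redundant_loading,
                 higher_order = higher_order, gamma = gamma,
                 tau_range = tau_range),
            class = "mist_pool_spec")
}

#' Simulate an item pool with planted structure
#'
#' Generates binary correctness data from a thresholded factor model:
#' item i is answered correctly when
#' `lambda_i * theta_F(i) + cross-terms + e_i > tau_i`, with unit total
#' latent variance per item. Junk items are pure noise; redundant pairs
#' share an extra minor factor. Veracity keys alternate by factor (odd
#' factors real, even factors fake; junk alternates) so the pool can feed
#' the veracity-aware selection pipeline.
#'
#' @param spec a [pool_spec()].
#' @param config a [sim_config()].
#' @return A list with `bank` (a custom `mist_bank`), `data` (0/1 matrix,
#'   respondents x items, correctness scored), and `truth` (per-item class
#'   labels, generating loadings, assignments, thresholds, redundant pairs,
#'   and the latent factor scores).
#' @export
simulate_item_pool <- function(spec, config) {
  stopifnot(inherits(spec, "mist_pool_spec"), inherits(config, "mist_sim_config"))
  n_items <- spec$n_factors * spec$items_per_factor + spec$n_junk +
    spec$n_crossloaded + 2 * spec$n_redundant_pairs
  if (n_items < spec$n_factors) mist_stop("spec_error",
    "pool has fewer items than factors")
  set.seed(config$seed)
  n <- config$n

  theta <- matrix(rnorm(n * spec$n_factors), n, spec$n_factors)
  if (spec$higher_order && spec$n_factors > 1) {
    g <- rnorm(n)
    theta <- spec$gamma * g + sqrt(1 - spec$gamma^2) * theta
  }

  ids <- character(n_items)
  class_lab <- character(n_items)
  assignment <- integer(n_items)
  lambda <- numeric(n_items)
  cross_to <- rep(NA_integer_, n_items)
  cross_lam <- rep(0, n_items)
  pair_id <- rep(NA_integer_, n_items)
  idx <- 0L
  for (f in seq_len(spec$n_factors)) {
    for (i in seq_len(spec$items_per_factor)) {
      idx <- idx + 1L
      ids[idx] <- sprintf("good_f%d_%02d", f, i)
      class_lab[idx] <- "good"; assignment[idx] <- f
      lambda[idx] <- runif(1, spec$loading_good[1], spec$loading_good[2])
    }
  }
  for (i in seq_len(spec$n_junk)) {
    idx <- idx + 1L
    ids[idx] <- sprintf("junk_%02d", i)
    class_lab[idx] <- "junk"; assignment[idx] <- 1L + (i - 1L) %% spec$n_factors
    lambda[idx] <- 0
  }
  for (i in seq_len(spec$n_crossloaded)) {
    idx <- idx + 1L
    f <- 1L + (i - 1L) %% spec$n_factors
    ids[idx] <- sprintf("cross_%02d", i)
    class_lab[idx] <- "crossloaded"; assignment[idx] <- f
    lambda[idx] <- runif(1, spec$loading_good[1], spec$loading_good[2]) * 0.8
    cross_to[idx] <- 1L + f %% spec$n_factors
    cross_lam[idx] <- runif(1, spec$crossloading[1], spec$crossloading[2])
  }
  for (pr in seq_len(spec$n_redundant_pairs)) {
    f <- 1L + (pr - 1L) %% spec$n_factors
    lam <- runif(1, spec$loading_good[1], spec$loading_good[2]) * 0.85
    for (half in 1:2) {
      idx <- idx + 1L
      ids[idx] <- sprintf("redund_%02d%s", pr, letters[half])
      class_lab[idx] <- "redundant"; assignment[idx] <- f
      lambda[idx] <- lam
      pair_id[idx] <- pr
    }
  }

  tau <- runif(n_items, spec$tau_range[1], spec$tau_range[2])
  minor <- if (spec$n_redundant_pairs > 0)
    matrix(rnorm(n * spec$n_redundant_pairs), n, spec$n_redundant_pairs) else NULL
  X <- matrix(0L, n, n_items, dimnames = list(NULL, ids))
  for (j in seq_len(n_items)) {
    lin <- lambda[j] * theta[, assignment[j]]
    extra_var <- lambda[j]^2
    if (!is.na(cross_to[j])) {
      lin <- lin + cross_lam[j] * theta[, cross_to[j]]
      extra_var <- extra_var + cross_lam[j]^2
    }
    if (!is.na(pair_id[j])) {
      lin <- lin + spec$redundant_loading * minor[, pair_id[j]]
      extra_var <- extra_var + spec$redundant_loading^2
    }
    e_sd <- sqrt(max(1 - extra_var, 0.05))
    X[, j] <- as.integer(lin + e_sd * rnorm(n) > tau[j])
  }

  # odd factors carry real-news items, even factors fake-news items
  veracity <- ifelse(assignment %% 2L == 1L, "real", "fake")
  bank <- new_bank(data.frame(id = ids, headline = paste("synthetic item", ids),
                              veracity = veracity, stringsAsFactors = FALSE),
                   name = "custom", version = paste0("seed-", config$seed))
  list(bank = bank, data = X,
       truth = list(class = setNames(class_lab, ids),
                    assignment = setNames(assignment, ids),
                    lambda = setNames(lambda, ids),
                    cross_to = setNames(cross_to, ids),
                    cross_loading = setNames(cross_lam, ids),
                    pair_id = setNames(pair_id, ids), tau = setNames(tau, ids),
                    theta = theta, seed = config$seed))
}
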