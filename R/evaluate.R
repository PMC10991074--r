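#' Paired pre/post intervention test
#'
#' Repeated-measures t-tests of post-minus-pre change for each
#' Verification-done dimension (V, r, f, d, n), with mean difference and
#' 95\% CI, and standardized effect sizes: `d_z` (mean difference over the
#' SD of the differences; `d_z * sqrt(n)` equals the paired t statistic)
#' and `d_av` (mean difference over the average of the pre and post SDs).
#' The effect-size CI is obtained from the noncentral t distribution of the
#' paired statistic. The five dimensions are reported uncorrected by
#' default, with an optional Holm adjustment.
#'
#' If pre and post are both constant and identical the test is reported as
#' a null result (t = 0, p = 1, d = 0); a nonzero constant difference has
#' no variance to test against and is an error.
#'
#' @param pre,post `mist_scores` data frames (aligned by `respondent_id`
#'   when present, otherwise by row), or plain numeric vectors for a single
#'   dimension.
#' @param dimensions which score columns to test.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return A data frame of class `mist_paired` with one row per dimension:
#'   `dimension`, `n`, `mean_diff`, `ci_lower`, `ci_upper`, `t`, `df`, `p`,
#'   `d_z`, `d_av`, `d_ci_lower`, `d_ci_upper`.
#' @export
paired_change_test <- function(pre, post, dimensions = c("V", "r", "f", "d", "n"),
                               p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  if (is.numeric(pre) && is.null(dim(pre))) {
    pre <- data.frame(score = pre); post <- data.frame(score = post)
    dimensions <- "score"
  }
  pre <- as.data.frame(pre); post <- as.data.frame(post)
  if ("respondent_id" %in% names(pre) && "respondent_id" %in% names(post)) {
    if (!setequal(pre$respondent_id, post$respondent_id)) {
      mist_stop("alignment_error", "pre and post respondent ids do not match")
    }
    post <- post[match(pre$respondent_id, post$respondent_id), , drop = FALSE]
  } else if (nrow(pre) != nrow(post)) {
    mist_stop("alignment_error", "pre and post have different numbers of rows")
  }
  n <- nrow(pre)
  if (n < 3) mist_stop("insufficient_n", "paired test needs at least 3 pairs")
  dimensions <- intersect(dimensions, intersect(names(pre), names(post)))
  rows <- lapply(dimensions, function(dm) {
    diffs <- post[[dm]] - pre[[dm]]
    sdd <- sd(diffs)
    if (sdd == 0) {
      if (all(diffs == 0)) {
        return(data.frame(dimension = dm, n = n, mean_diff = 0, ci_lower = 0,
                          ci_upper = 0, t = 0, df = n - 1L, p = 1, d_z = 0,
                          d_av = 0, d_ci_lower = 0, d_ci_upper = 0,
                          stringsAsFactors = FALSE))
      }
      mist_stop("degenerate_variance", paste0(
        "differences for ", dm, " are constant and nonzero"))
    }
    tt <- t.test(diffs, mu = 0)
    d_z <- mean(diffs) / sdd
    d_av <- mean(diffs) / mean(c(sd(pre[[dm]]), sd(post[[dm]])))
    tstat <- unname(tt$statistic)
    dfree <- unname(tt$parameter)
    # noncentrality CI for the paired statistic -> effect-size CI
    ncp_root <- function(prob) tryCatch(suppressWarnings(uniroot(
      function(nc) pt(tstat, dfree, ncp = nc) - prob,
      interval = c(tstat - 40, tstat + 40), extendInt = "yes")$root),
      error = function(e) NA_real_)
    ncp_lo <- ncp_root(0.975)
    ncp_hi <- ncp_root(0.025)
    data.frame(dimension = dm, n = n, mean_diff = mean(diffs),
               ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
               t = tstat, df = dfree, p = tt$p.value, d_z = d_z, d_av = d_av,
               d_ci_lower = ncp_lo / sqrt(n), d_ci_upper = ncp_hi / sqrt(n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "holm") out$p_holm <- p.adjust(out$p, "holm")
  class(out) <- c("mist_paired", "data.frame")
  out
}

#' @export
print.mist_paired <- function(x, ...) {
  cat(sprintf("<paired change test> n = %d pair(s)\n", x$n[1]))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, 3)
  print(df)
  invisible(x)
}

#' Sample size for a two-sample t-test
#'
#' Solves for the per-group sample size of an independent two-sample
#' t-test with the given standardized effect size (Cohen's d), under the
#' noncentral t distribution of the test statistic.
#'
#' @param d standardized effect size (> 0).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return A list with `n_real` (the exact solution) and `n_int`
#'   (`ceiling(n_real)`, the per-group recruitment target).
#' @examples
#' required_n_ttest(d = 0.25, alpha = 0.05, power = 0.90)$n_int  # 338
#' @export
required_n_ttest <- function(d, alpha = 0.05, power = 0.90) {
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  if (power <= alpha) mist_stop("infeasible",
    "target power must exceed the significance level")
  n_real <- power.t.test(delta = d, sd = 1, sig.level = alpha, power = power,
                         type = "two.sample", alternative = "two.sided")$n
  list(n_real = n_real, n_int = as.integer(ceiling(n_real)))
}

#' Sample size for a correlation test
#'
#' Fisher-z approximation for detecting a population correlation `r`:
#' `n = ((z_{1-alpha/2} + z_{power}) / atanh(r))^2 + 3`.
#'
#' @param r the smallest correlation of interest (0 < |r| < 1).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return A list with `n_real` and `n_int = ceiling(n_real)`.
#' @examples
#' required_n_correlation(r = 0.15, alpha = 0.05, power = 0.90)$n_int  # 463
#' @export
required_n_correlation <- function(r, alpha = 0.05, power = 0.90) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  if (abs(r) >= 1 || r == 0) mist_stop("effect_error",
    "correlation effect size must satisfy 0 < |r| < 1")
  if (power <= alpha) mist_stop("infeasible",
    "target power must exceed the significance level")
  n_real <- ((qnorm(1 - alpha / 2) + qnorm(power)) / atanh(abs(r)))^2 + 3
  list(n_real = n_real, n_int = as.integer(ceiling(n_real)))
}

#' Incremental validity regression
#'
#' Ordinary least squares on standardized variables: fits the outcome on a
#' base predictor set and on base + added predictors, reporting adjusted
#' R-squared for both models, their difference, and the full model's
#' standardized coefficients with 95\% CIs. Used to ask how much variance a
#' new scale explains beyond established measures.
#'
#' @param outcome numeric vector.
#' @param base data frame/matrix of base predictors (may be NULL or empty
#'   for an intercept-only base).
#' @param added data frame/matrix of predictors added on top.
#' @return A list of class `mist_incremental`: `adj_r2_base`,
#'   `adj_r2_full`, `delta_r2` (difference of adjusted R-squared),
#'   `r2_base`, `r2_full`, `coefficients` (full model, with CIs), `n`.
#' @export
incremental_validity <- function(outcome, base = NULL, added) {
  y <- as.numeric(outcome)
  base_df <- if (is.null(base)) NULL else as.data.frame(base)
  added_df <- as.data.frame(added)
  dat <- data.frame(.y = y)
  if (!is.null(base_df)) dat <- cbind(dat, base_df)
  dat <- cbind(dat, added_df)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  p_full <- ncol(dat) - 1
  if (n <= p_full + 2) mist_stop("insufficient_n",
    "need more complete cases than predictors + 2")
  dat[] <- lapply(dat, function(col) as.numeric(scale(col)))
  base_terms <- if (is.null(base_df)) character(0) else names(base_df)
  full_terms <- c(base_terms, names(added_df))
  form <- function(terms) stats::as.formula(paste(
    ".y ~", if (length(terms)) paste(terms, collapse = " + ") else "1"))
  fit_base <- lm(form(base_terms), data = dat)
  fit_full <- lm(form(full_terms), data = dat)
  if (fit_full$rank < length(full_terms) + 1) mist_stop("collinearity",
    "full predictor matrix is rank deficient")
  s_base <- summary(fit_base); s_full <- summary(fit_full)
  ci <- stats::confint(fit_full)
  coefs <- data.frame(term = rownames(s_full$coefficients),
                      beta = s_full$coefficients[, 1],
                      se = s_full$coefficients[, 2],
                      t = s_full$coefficients[, 3],
                      p = s_full$coefficients[, 4],
                      ci_lower = ci[, 1], ci_upper = ci[, 2],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(adj_r2_base = s_base$adj.r.squared,
                 adj_r2_full = s_full$adj.r.squared,
                 delta_r2 = s_full$adj.r.squared - s_base$adj.r.squared,
                 r2_base = s_base$r.squared, r2_full = s_full$r.squared,
                 coefficients = coefs, n = n),
            class = "mist_incremental")
}

#' @export
print.mist_incremental <- function(x, ...) {
  cat(sprintf("<incremental validity> n = %d\n", x$n))
  cat(sprintf("  adjusted R2: base %.3f -> full %.3f (delta %.3f)\n",
              x$adj_r2_base, x$adj_r2_full, x$delta_r2))
  df <- x$coefficients
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, 3)
  print(df)
  invisible(x)
}
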