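#' Population norm tables
#'
#' Norm tables contextualize individual or cohort scores against a national
#' reference sample. A norm table carries, per scored dimension (overall
#' veracity discernment `V`, fake-news detection `f`, real-news detection
#' `r`), a percentile-to-score grid on the 0-100-by-5 percentile grid and/or
#' a quartile summary (min, Q1, median, mean, Q3, max).
#'
#' `builtin_norms()` returns the packaged US/UK general-population norms:
#' the full US MIST-20 grids for V, f and r, and quartile summaries for the
#' US and UK on both the MIST-20 and MIST-8.
#'
#' @param country `"US"` or `"UK"`.
#' @param scale `"MIST-20"` or `"MIST-8"`.
#' @return An object of class `mist_norms`: a list with `country`, `scale`,
#'   `n` (reference-sample size, when known), `grids` (named list of data
#'   frames with columns `percentile`, `score`), and `quartiles` (named list
#'   of quartile summaries per dimension).
#' @examples
#' norms <- builtin_norms("US", "MIST-20")
#' score_at_percentile(norms, "V", 50)
#' @export
builtin_norms <- function(country = c("US", "UK"), scale = c("MIST-20", "MIST-8")) {
  country <- match.arg(country)
  scale <- match.arg(scale)
  grids <- list()
  n <- NA_integer_
  if (country == "US" && scale == "MIST-20") {
    raw <- jsonlite::read_json(system.file("extdata", "norms_us_mist20.json",
                                           package = "mistkit"))
    n <- raw$n
    grids <- lapply(raw$grids, function(g) data.frame(
      percentile = vapply(g$percentile, as.numeric, 0),
      score = vapply(g$score, as.numeric, 0)))
  }
  qraw <- jsonlite::read_json(system.file("extdata", "quartiles_us_uk.json",
                                          package = "mistkit"))
  quartiles <- list()
  for (tab in qraw$tables) {
    if (tab$country == country && tab$scale == scale) {
      quartiles[[tab$dimension]] <- unlist(tab[c("min", "q1", "median", "mean", "q3", "max")])
    }
  }
  new_norms(country = country, scale = scale, grids = grids,
            quartiles = quartiles, n = n)
}

#' @param grids named list (`V`, `f`, `r`) of data frames with columns
#'   `percentile` (0 to 100 in steps of 5) and non-decreasing integer `score`.
#' @param quartiles named list of quartile vectors
#'   (`min`, `q1`, `median`, `mean`, `q3`, `max`).
#' @param n reference-sample size.
#' @rdname builtin_norms
#' @export
new_norms <- function(country, scale, grids = list(), quartiles = list(), n = NA) {
  k <- if (scale == "MIST-8") 8L else if (scale == "MIST-16") 16L else 20L
  for (dim in names(grids)) {
    g <- grids[[dim]]
    stopifnot(is.data.frame(g), all(c("percentile", "score") %in% names(g)))
    if (!identical(as.numeric(g$percentile), seq(0, 100, by = 5))) {
      mist_stop("parse_error", paste0("norm grid for ", dim,
        " must cover percentiles 0-100 in steps of 5"))
    }
    if (any(diff(g$score) < 0)) {
      mist_stop("parse_error", paste0("norm grid scores for ", dim,
        " must be non-decreasing in percentile"))
    }
    hi <- if (dim == "V") k else k %/% 2L
    if (any(g$score < 0 | g$score > hi)) {
      mist_stop("parse_error", paste0("norm grid scores for ", dim,
        " outside the dimension range [0, ", hi, "]"))
    }
  }
  structure(list(country = country, scale = scale, n = n, grids = grids,
                 quartiles = quartiles), class = "mist_norms")
}

#' Norm-table reads
#'
#' `score_at_percentile()` is an exact table read: the score attained at a
#' grid percentile. `percentile_rank()` is its inverse: the largest grid
#' percentile whose table score does not exceed the given score (0 if none
#' qualifies). The tie convention matters because the published tables repeat
#' scores across adjacent percentiles; ties resolve to the largest
#' qualifying percentile.
#'
#' @param norms a `mist_norms` with a grid for `dimension`.
#' @param dimension `"V"`, `"f"` or `"r"`.
#' @param percentile a value on the 0-100-by-5 grid (no interpolation).
#' @param score an integer score within the dimension's range.
#' @return An integer score, resp. a grid percentile.
#' @export
score_at_percentile <- function(norms, dimension = c("V", "f", "r"), percentile) {
  stopifnot(inherits(norms, "mist_norms"))
  dimension <- match.arg(dimension)
  g <- norms$grids[[dimension]]
  if (is.null(g)) mist_stop("off_grid", paste0(
    "no percentile grid for dimension ", dimension, " in ",
    norms$country, " ", norms$scale, " norms"))
  i <- match(percentile, g$percentile)
  if (is.na(i)) mist_stop("off_grid", paste0(
    "percentile ", percentile, " is off the 0-100-by-5 grid"))
  as.integer(g$score[i])
}

#' @rdname score_at_percentile
#' @export
percentile_rank <- function(norms, dimension = c("V", "f", "r"), score) {
  stopifnot(inherits(norms, "mist_norms"))
  dimension <- match.arg(dimension)
  g <- norms$grids[[dimension]]
  if (is.null(g)) mist_stop("off_grid", paste0(
    "no percentile grid for dimension ", dimension, " in ",
    norms$country, " ", norms$scale, " norms"))
  k <- if (norms$scale == "MIST-8") 8L else 20L
  hi <- if (dimension == "V") k else k %/% 2L
  if (score < 0 || score > hi) mist_stop("range_error", paste0(
    "score ", score, " outside the ", dimension, " range [0, ", hi, "]"))
  ok <- which(g$score <= score)
  if (length(ok) == 0) return(0)
  max(g$percentile[ok])
}

#' Cohort norm report
#'
#' Juxtaposes a cohort's score quartiles with the population norm quartiles,
#' per dimension, and flags dimensions where the cohort's first quartile
#' exceeds the population's (an above-norm baseline, relevant when a
#' convenience sample starts above the general population).
#'
#' @param scores a `mist_scores` data frame from [score_matrix()] (or any
#'   data frame with columns `V`, `r`, `f`).
#' @param norms a `mist_norms` carrying quartiles.
#' @return A list of class `mist_norm_report` with `sample` and `population`
#'   quartile tables and a character vector `flags`.
#' @export
cohort_norm_report <- function(scores, norms) {
  stopifnot(inherits(norms, "mist_norms"))
  scores <- as.data.frame(scores)
  if (nrow(scores) < 4) mist_stop("insufficient_n",
    "cohort norm report needs at least 4 respondents")
  dims <- intersect(c("V", "r", "f"), names(scores))
  samp <- t(vapply(dims, function(d) {
    x <- scores[[d]]
    c(min = min(x), q1 = unname(quantile(x, 0.25)), median = median(x),
      mean = mean(x), q3 = unname(quantile(x, 0.75)), max = max(x))
  }, numeric(6)))
  pop <- norms$quartiles
  flags <- character(0)
  for (d in dims) {
    if (!is.null(pop[[d]]) && samp[d, "q1"] > pop[[d]][["q1"]]) {
      flags <- c(flags, paste0(d, ": above-norm baseline (sample Q1 = ",
                               samp[d, "q1"], " > population Q1 = ",
                               pop[[d]][["q1"]], ")"))
    }
  }
  structure(list(sample = samp, population = pop, flags = flags,
                 country = norms$country, scale = norms$scale),
            class = "mist_norm_report")
}

#' @export
print.mist_norms <- function(x, ...) {
  cat(sprintf("<mist_norms> %s %s general population%s\n", x$country, x$scale,
              if (!is.na(x$n)) paste0(" (N = ", x$n, ")") else ""))
  if (length(x$grids)) cat("  percentile grids:", paste(names(x$grids), collapse = ", "), "\n")
  if (length(x$quartiles)) cat("  quartiles:", paste(names(x$quartiles), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.mist_norm_report <- function(x, ...) {
  cat(sprintf("<cohort norm report> vs %s %s norms\n", x$country, x$scale))
  print(round(x$sample, 2))
  if (length(x$flags)) for (f in x$flags) cat("  flag:", f, "\n")
  else cat("  no above-norm flags\n")
  invisible(x)
}
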