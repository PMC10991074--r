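#' Verification-done scoring
#'
#' Scores binary real/fake judgments against a bank's veracity keys into the
#' five Verification-done quantities:
#' \describe{
#'   \item{V}{veracity discernment: total items answered correctly, `V = r + f`.}
#'   \item{r}{real-news detection: real items labeled `"real"`.}
#'   \item{f}{fake-news detection: fake items labeled `"fake"`.}
#'   \item{d}{distrust bias: excess of `"fake"` labels over the number of
#'     fake items, `d = max(0, #fake-labels - k_fake)`.}
#'   \item{n}{naivete bias: excess of `"real"` labels over the number of real
#'     items, `n = max(0, #real-labels - k_real)`.}
#' }
#' At most one of `d`/`n` can be positive, and on a balanced bank
#' `d - n = f - r`. The d/n formulas follow from the model's semantics
#' (over-labeling fake = overly skeptical); the published scale description
#' announces the bias scores and defers the exact formula to its scoring
#' guide, so the counting rule here is documented rather than assumed known.
#'
#' @param bank a `mist_bank`.
#' @param labels a named character vector: names are item ids (a subset of
#'   the bank's), values `"real"`, `"fake"` or `NA`.
#' @param allow_missing if `FALSE` (default), missing labels are an error;
#'   if `TRUE`, only answered items are scored and `V_prorated`
#'   (`V * k / answered`) and `prop_answered` are attached.
#' @param respondent_id optional id carried into the result.
#' @return A one-row data frame of class `mist_scores` with columns
#'   `respondent_id`, `V`, `r`, `f`, `d`, `n`, `k` (items scored), `k_real`,
#'   `k_fake` (and `V_prorated`, `prop_answered` in permissive mode).
#' @examples
#' bank <- builtin_bank("MIST-8")
#' key <- setNames(bank$items$veracity, bank$items$id)
#' score_responses(bank, key)  # a perfect respondent
#' @export
score_responses <- function(bank, labels, allow_missing = FALSE,
                            respondent_id = NA_character_) {
  stopifnot(inherits(bank, "mist_bank"))
  ids <- bank$items$id
  if (is.null(names(labels))) {
    if (length(labels) == length(ids)) names(labels) <- ids
    else mist_stop("id_mismatch", "labels must be named by item id")
  }
  unknown <- setdiff(names(labels), ids)
  if (length(unknown) > 0) mist_stop("id_mismatch", paste0(
    "labels for items not in the bank: ", paste(unknown, collapse = ", ")))
  lab <- rep(NA_character_, length(ids))
  names(lab) <- ids
  lab[names(labels)] <- as.character(labels)
  bad <- !is.na(lab) & !lab %in% c("real", "fake")
  if (any(bad)) mist_stop("parse_error", paste0(
    "labels must be \"real\", \"fake\" or NA; offending item(s): ",
    paste(ids[bad], collapse = ", ")))
  answered <- !is.na(lab)
  if (!any(answered)) mist_stop("empty_response", "all labels are missing")
  if (!allow_missing && !all(answered)) mist_stop("incomplete_response", paste0(
    sum(!answered), " missing label(s); score with allow_missing = TRUE to ",
    "prorate over answered items"))

  key <- bank$items$veracity
  k_real <- sum(key[answered] == "real")
  k_fake <- sum(key[answered] == "fake")
  k <- sum(answered)
  r <- sum(answered & key == "real" & lab == "real")
  f <- sum(answered & key == "fake" & lab == "fake")
  n_fake_labels <- sum(answered & lab == "fake")
  n_real_labels <- sum(answered & lab == "real")
  out <- data.frame(respondent_id = respondent_id,
                    V = r + f, r = r, f = f,
                    d = max(0L, n_fake_labels - k_fake),
                    n = max(0L, n_real_labels - k_real),
                    k = k, k_real = k_real, k_fake = k_fake,
                    stringsAsFactors = FALSE)
  if (allow_missing) {
    out$prop_answered <- k / nrow(bank$items)
    out$V_prorated <- if (k > 0) (r + f) * nrow(bank$items) / k else NA_real_
  }
  class(out) <- c("mist_scores", "data.frame")
  out
}

#' Score a table of respondents
#'
#' Vectorized [score_responses()] over a wide response table (one row per
#' respondent, one column per item id, cell values `"real"`/`"fake"`/`NA`).
#' Row order is preserved and a per-dimension mean/SD summary is attached as
#' the `"summary"` attribute.
#'
#' @param bank a `mist_bank`.
#' @param responses a data frame or matrix; a `respondent_id` column is used
#'   as ids if present, otherwise row names / indices are used. All other
#'   columns must be bank item ids.
#' @param allow_missing passed to [score_responses()].
#' @return A `mist_scores` data frame, one row per respondent, with a
#'   `"summary"` attribute (mean and SD of V, r, f, d, n).
#' @export
score_matrix <- function(bank, responses, allow_missing = FALSE) {
  responses <- as.data.frame(responses, stringsAsFactors = FALSE)
  if ("respondent_id" %in% names(responses)) {
    ids <- as.character(responses$respondent_id)
    responses <- responses[, setdiff(names(responses), "respondent_id"), drop = FALSE]
  } else {
    ids <- rownames(responses) %||% as.character(seq_len(nrow(responses)))
  }
  rows <- vector("list", nrow(responses))
  for (i in seq_len(nrow(responses))) {
    labels <- unlist(responses[i, , drop = TRUE])
    names(labels) <- names(responses)
    rows[[i]] <- tryCatch(
      score_responses(bank, labels, allow_missing = allow_missing,
                      respondent_id = ids[i]),
      mistkit_error = function(e) mist_stop(
        class(e)[1], paste0("row ", i, " (", ids[i], "): ", conditionMessage(e))))
  }
  out <- do.call(rbind, rows)
  dims <- c("V", "r", "f", "d", "n")
  attr(out, "summary") <- data.frame(
    dimension = dims,
    mean = vapply(dims, function(d) mean(out[[d]]), 0),
    sd = vapply(dims, function(d) sd(out[[d]]), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("mist_scores", "data.frame")
  out
}

#' Read a wide responses CSV
#'
#' Column `respondent_id` then one column per item id; cells are
#' `real`/`fake`/`NA`.
#'
#' @param path CSV file path.
#' @return A data frame suitable for [score_matrix()].
#' @export
read_responses <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
           colClasses = "character", na.strings = c("NA", ""))
}

#' @export
print.mist_scores <- function(x, ...) {
  cat(sprintf("<mist_scores> %d respondent(s), k = %s\n", nrow(x),
              paste(unique(x$k), collapse = "/")))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  s <- attr(x, "summary")
  if (!is.null(s)) {
    cat("  summary:\n")
    print.data.frame(transform(s, mean = round(mean, 3), sd = round(sd, 3)))
  }
  invisible(x)
}
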