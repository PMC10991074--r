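#' Item banks
#'
#' An item bank is the unit of test administration in mistkit: an ordered set
#' of news headlines, each with a veracity key (`"real"` or `"fake"`) and,
#' when calibrated, three-parameter-logistic (3PL) discrimination (`a`),
#' difficulty (`b`) and guessing (`c`, fixed at 0.5 for a binary real/fake
#' judgment) parameters. The published banks are available via
#' [builtin_bank()]; custom pools are constructed with `new_bank()` or read
#' from JSON with [load_bank()].
#'
#' @param items a data frame with columns `id`, `headline`, `veracity`
#'   (`"real"`/`"fake"`) and optionally `a`, `b`, `c`, `ega_dimension`.
#' @param name bank name; one of `"MIST-20"`, `"MIST-16"`, `"MIST-8"` for the
#'   published banks, anything else is treated as `"custom"`.
#' @param version free-form version string.
#' @return An object of class `mist_bank`: a list with elements `name`,
#'   `version` and `items` (a data frame, one row per item in administration
#'   order).
#' @examples
#' bank <- builtin_bank("MIST-8")
#' bank
#' @export
new_bank <- function(items, name = "custom", version = "1.0") {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  required <- c("id", "headline", "veracity")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    mist_stop("parse_error", paste0(
      "bank items lack required field(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (col in c("a", "b", "c")) if (!col %in% names(items)) items[[col]] <- NA_real_
  if (!"ega_dimension" %in% names(items)) items$ega_dimension <- NA_integer_
  items$id <- as.character(items$id)
  items$headline <- as.character(items$headline)
  items$veracity <- as.character(items$veracity)
  bad_ver <- !items$veracity %in% c("real", "fake")
  if (any(bad_ver)) {
    mist_stop("parse_error", paste0(
      "field 'veracity' must be \"real\" or \"fake\"; offending item(s): ",
      paste(items$id[bad_ver], collapse = ", ")))
  }
  dup <- items$id[duplicated(items$id)]
  if (length(dup) > 0) {
    mist_stop("parse_error", paste0(
      "field 'id' has duplicate value(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (any(!is.na(items$a) & items$a <= 0)) {
    mist_stop("parse_error", "field 'a' (discrimination) must be > 0 where present")
  }
  if (any(!is.na(items$c) & (items$c < 0 | items$c >= 1))) {
    mist_stop("parse_error", "field 'c' (guessing) must lie in [0, 1)")
  }
  rownames(items) <- NULL
  structure(
    list(name = as.character(name)[1], version = as.character(version)[1],
         items = items[, c("id", "headline", "veracity", "a", "b", "c", "ega_dimension")]),
    class = "mist_bank")
}

.item_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    path <- system.file("extdata", "mist_items.json", package = "mistkit")
    raw <- jsonlite::read_json(path)
    rows <- lapply(raw$items, function(it) {
      data.frame(
        id = it$id, headline = it$headline, veracity = it$veracity,
        a = as.numeric(.fld(it, "a")), b = as.numeric(.fld(it, "b")),
        c = as.numeric(.fld(it, "c")),
        mist20 = isTRUE(it$mist20), mist8 = isTRUE(it$mist8),
        ega_dimension = as.integer(.fld(it, "ega_dimension", NA_integer_)),
        mist16_order = as.integer(.fld(it, "mist16_order", NA_integer_)),
        stringsAsFactors = FALSE)
    })
    cache <<- do.call(rbind, rows)
    cache
  }
})

#' Published MIST item banks
#'
#' Returns one of the published banks: the 20-item full scale (`"MIST-20"`,
#' 10 real + 10 fake with 3PL `a`/`b` and `c = 0.5`), its 8-item short form
#' (`"MIST-8"`, 4 real + 4 fake, a subset of the MIST-20), or the 16-item
#' four-dimension scale selected via exploratory graph analysis
#' (`"MIST-16"`, 8 real + 8 fake with dimension labels 1-4).
#'
#' @param name `"MIST-20"`, `"MIST-16"` or `"MIST-8"`.
#' @return A [new_bank()] object.
#' @examples
#' builtin_bank("MIST-20")$items[1:3, c("id", "a", "b")]
#' @export
builtin_bank <- function(name = c("MIST-20", "MIST-16", "MIST-8")) {
  if (!is.character(name) || length(name) != 1 || !name %in% c("MIST-20", "MIST-16", "MIST-8")) {
    mist_stop("invalid_bank_name", paste0(
      "unknown bank name ", deparse(substitute(name)), "; expected \"MIST-20\", \"MIST-16\" or \"MIST-8\""))
  }
  tab <- .item_table()
  items <- switch(name,
    "MIST-20" = tab[tab$mist20, ],
    "MIST-8"  = tab[tab$mist8, ],
    "MIST-16" = { m <- tab[!is.na(tab$mist16_order), ]; m[order(m$mist16_order), ] })
  if (name != "MIST-16") items$ega_dimension <- NA_integer_
  if (name == "MIST-16") items[, c("a", "b", "c")] <- NA_real_
  new_bank(items[, c("id", "headline", "veracity", "a", "b", "c", "ega_dimension")],
           name = name, version = "1.0")
}

#' Read and write bank JSON
#'
#' Banks serialize to a UTF-8 JSON document
#' `{"name", "version", "items": [{"id", "headline", "veracity", "a", "b",
#' "c", "ega_dimension"}, ...]}`. The round trip is lossless.
#'
#' @param path file path.
#' @param bank a `mist_bank`.
#' @return `load_bank()` returns a validated `mist_bank`; `write_bank()`
#'   returns `path` invisibly.
#' @export
load_bank <- function(path) {
  if (!file.exists(path)) mist_stop("parse_error", paste0("no such file: ", path))
  raw <- tryCatch(jsonlite::read_json(path),
                  error = function(e) mist_stop("parse_error",
                    paste0("malformed JSON in ", path, ": ", conditionMessage(e))))
  if (is.null(raw$items)) mist_stop("parse_error", "bank JSON lacks an \"items\" array")
  rows <- lapply(raw$items, function(it) {
    for (f in c("id", "headline", "veracity")) {
      if (is.null(it[[f]])) mist_stop("parse_error", paste0("item lacks required field '", f, "'"))
    }
    data.frame(id = it$id, headline = it$headline, veracity = it$veracity,
               a = as.numeric(.fld(it, "a")), b = as.numeric(.fld(it, "b")),
               c = as.numeric(.fld(it, "c")),
               ega_dimension = as.integer(.fld(it, "ega_dimension", NA_integer_)),
               stringsAsFactors = FALSE)
  })
  new_bank(do.call(rbind, rows), name = .fld(raw, "name", "custom"),
           version = .fld(raw, "version", "1.0"))
}

#' @rdname load_bank
#' @export
write_bank <- function(bank, path) {
  stopifnot(inherits(bank, "mist_bank"))
  items <- lapply(seq_len(nrow(bank$items)), function(i) {
    row <- bank$items[i, ]
    out <- list(id = row$id, headline = row$headline, veracity = row$veracity)
    if (!is.na(row$a)) out$a <- row$a
    if (!is.na(row$b)) out$b <- row$b
    if (!is.na(row$c)) out$c <- row$c
    if (!is.na(row$ega_dimension)) out$ega_dimension <- row$ega_dimension
    out
  })
  jsonlite::write_json(list(name = bank$name, version = bank$version, items = items),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Validate an item bank
#'
#' Checks real/fake balance, parameter completeness and the defining
#' invariants of the named banks (MIST-20: 10+10; MIST-8: 4+4 and a subset of
#' the MIST-20; MIST-16: 8+8 in four dimensions of sizes 5/5/3/3). Failures
#' and warnings are carried in the returned report rather than signalled.
#'
#' @param bank a `mist_bank`.
#' @return A list of class `mist_bank_validation` with elements `name`,
#'   `n_items`, `n_real`, `n_fake`, `balanced`, `has_params`, `checks`
#'   (data frame of named checks with pass flags), `warnings`, and `pass`.
#' @export
validate_bank <- function(bank) {
  stopifnot(inherits(bank, "mist_bank"))
  it <- bank$items
  n_real <- sum(it$veracity == "real")
  n_fake <- sum(it$veracity == "fake")
  balanced <- n_real == n_fake
  has_params <- all(!is.na(it$a) & !is.na(it$b))
  checks <- list()
  add <- function(name, pass) checks[[length(checks) + 1L]] <<- data.frame(
    check = name, pass = pass, stringsAsFactors = FALSE)
  warnings <- character(0)

  add("unique ids", !anyDuplicated(it$id))
  add("veracity keys present", all(it$veracity %in% c("real", "fake")))
  if (any(!is.na(it$c))) add("guessing fixed at 0.5", all(abs(it$c[!is.na(it$c)] - 0.5) < 1e-12))

  if (bank$name == "MIST-20") {
    add("20 items", nrow(it) == 20)
    add("balance 10 real : 10 fake", n_real == 10 && n_fake == 10)
    add("3PL parameters complete", has_params)
  } else if (bank$name == "MIST-8") {
    add("8 items", nrow(it) == 8)
    add("balance 4 real : 4 fake", n_real == 4 && n_fake == 4)
    add("subset of MIST-20", all(it$id %in% builtin_bank("MIST-20")$items$id))
    add("3PL parameters complete", has_params)
  } else if (bank$name == "MIST-16") {
    add("16 items", nrow(it) == 16)
    add("balance 8 real : 8 fake", n_real == 8 && n_fake == 8)
    dims <- table(factor(it$ega_dimension, levels = 1:4))
    add("dimension sizes 5/5/3/3", all(dims == c(5L, 5L, 3L, 3L)))
    add("dimensions 1/4 real, 2/3 fake",
        all(it$veracity[it$ega_dimension %in% c(1, 4)] == "real") &&
        all(it$veracity[it$ega_dimension %in% c(2, 3)] == "fake"))
  }
  if (!balanced) {
    warnings <- c(warnings, paste0(
      "unbalanced bank (", n_real, " real : ", n_fake,
      " fake); d/n bias scores are still defined but V interpretation differs"))
  }
  checks <- do.call(rbind, checks)
  structure(list(name = bank$name, n_items = nrow(it), n_real = n_real,
                 n_fake = n_fake, balanced = balanced, has_params = has_params,
                 checks = checks, warnings = warnings, pass = all(checks$pass)),
            class = "mist_bank_validation")
}

#' @export
print.mist_bank <- function(x, ...) {
  n_real <- sum(x$items$veracity == "real")
  n_fake <- sum(x$items$veracity == "fake")
  cat(sprintf("<mist_bank> %s (v%s): %d items (%d real, %d fake)\n",
              x$name, x$version, nrow(x$items), n_real, n_fake))
  if (any(!is.na(x$items$a))) {
    cat(sprintf("  3PL parameters: a in [%.2f, %.2f], b in [%.2f, %.2f], c = %.2g\n",
                min(x$items$a, na.rm = TRUE), max(x$items$a, na.rm = TRUE),
                min(x$items$b, na.rm = TRUE), max(x$items$b, na.rm = TRUE),
                unique(x$items$c[!is.na(x$items$c)])[1]))
  }
  if (any(!is.na(x$items$ega_dimension))) {
    cat("  EGA dimensions:",
        paste(names(table(x$items$ega_dimension)), table(x$items$ega_dimension),
              sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
print.mist_bank_validation <- function(x, ...) {
  cat(sprintf("<bank validation> %s: %d items (%d real : %d fake) -- %s\n",
              x$name, x$n_items, x$n_real, x$n_fake,
              if (x$pass) "PASS" else "FAIL"))
  for (i in seq_len(nrow(x$checks))) {
    cat(sprintf("  [%s] %s\n", if (x$checks$pass[i]) "ok" else "XX", x$checks$check[i]))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
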