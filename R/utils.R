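#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate coef cor cov dnorm integrate lm logLik median
#'   optim optimise optimize p.adjust pchisq pnorm pt power.t.test qnorm qt
#'   quantile rbinom rnorm runif sd setNames t.test uniroot var
#' @importFrom utils head tail read.csv write.csv
#' @importFrom graphics abline legend lines matplot
NULL

# classed error helper: every signalled condition carries a "mistkit_<class>"
# condition class so callers (and tests) can match on it
mist_stop <- function(class, msg, call. = FALSE) {
  cnd <- structure(
    class = c(paste0("mistkit_", class), "mistkit_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cnd)
}

mist_warn <- function(class, msg) {
  cnd <- structure(
    class = c(paste0("mistkit_", class), "mistkit_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  )
  warning(cnd)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# scalar NA-tolerant fetch from a list
.fld <- function(x, name, default = NA) {
  v <- x[[name]]
  if (is.null(v) || length(v) == 0) default else v
}
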