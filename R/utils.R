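#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-scale values (may contain -Inf).
#' @return log(sum(exp(x))) computed without underflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical string key for a vertex, used to deduplicate evaluated vertices
# across search iterations. Coordinates are snapped to 1e-9 so that
# floating-point noise from repeated +/- 1/m arithmetic cannot split keys.
vertex_key <- function(h2) {
  paste(sprintf("%.9f", round(h2 * 1e9) / 1e9), collapse = ",")
}

# format a double so that read.table() recovers it bit-exactly
fmt17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

gv_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
  }
  invisible(NULL)
}
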