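#' Derive a reproducible integer seed from a root seed and string tags
#'
#' Folds the root seed and any number of tags (sample id, day, replicate, ...)
#' into a 31-bit integer with a multiplicative byte hash, so that regenerating
#' any subset of a study (one run, one sample) is stable under the same root
#' seed without consuming a shared random stream.
#'
#' @param root integer root seed.
#' @param ... further tags (coerced to character).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(root, ...) {
  s <- paste(c(as.character(root), vapply(list(...), as.character, "")),
             collapse = "\r")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_evoofuse <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "evoofuse_error")))
}

#' @keywords internal
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
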