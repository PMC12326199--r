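#' Internal condition helper
#'
#' All package errors are classed so callers (and the pipeline driver) can
#' distinguish validation problems from numerical ones.
#'
#' @noRd
abort_chromatch <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "chromatch_error"), ...)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopifnot_scalar_positive <- function(x, what) {
  if (!is_scalar_number(x) || x <= 0) {
    abort_chromatch(sprintf("`%s` must be a single positive finite number.", what),
                    "chromatch_domain_error")
  }
  invisible(x)
}
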