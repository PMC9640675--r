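#' @keywords internal
#' Classed error helpers. Every user-facing failure carries one of the
#' condition classes below so callers (and the CLI dispatcher) can map error
#' classes to exit codes without parsing messages.
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "trichoproj_error")))
}

abort_domain <- function(msg) abort(msg, "trichoproj_domain_error")
abort_config <- function(msg) abort(msg, "trichoproj_config_error")
abort_shape  <- function(msg) abort(msg, "trichoproj_shape_error")
abort_format <- function(msg) abort(msg, "trichoproj_format_error")
abort_io     <- function(msg) abort(msg, "trichoproj_io_error")

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_domain(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}
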