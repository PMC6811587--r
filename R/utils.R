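# Internal error helpers: every user-facing failure carries a subclass so
# callers (and the CLI) can distinguish usage, format, and validation errors.

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = "flowhier_format_error", ...)
}

abort_referential <- function(msg, ...) {
  rlang::abort(msg, class = "flowhier_referential_error", ...)
}

abort_domain <- function(msg, ...) {
  rlang::abort(msg, class = "flowhier_domain_error", ...)
}

abort_empty <- function(msg, ...) {
  rlang::abort(msg, class = "flowhier_empty_network_error", ...)
}

abort_degenerate <- function(msg, ...) {
  rlang::abort(msg, class = "flowhier_degenerate_error", ...)
}

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "flowhier_validation_error", ...)
}

abort_allocation <- function(msg, ...) {
  rlang::abort(msg, class = "flowhier_allocation_error", ...)
}

`%||%` <- rlang::`%||%`

# scalar checks used across modules
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_domain(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}
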